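#' @name accessors
#' @title Accessors for chaosgm data classes
#' @description Slot accessors for the S4 containers: image data, affines,
#'   subject ids, series values and voxel bookkeeping, scalogram coefficients.
#' @param object A chaosgm S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(object) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("voxelIndices", function(object) standardGeneric("voxelIndices"))
#' @rdname accessors
#' @export
setGeneric("scalCoeffs", function(object) standardGeneric("scalCoeffs"))
#' @rdname accessors
#' @export
setGeneric("scalScales", function(object) standardGeneric("scalScales"))
#' @rdname accessors
#' @export
setGeneric("boundaryMask", function(object) standardGeneric("boundaryMask"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
setMethod("volData", "GMVolume", function(object) object@data)
#' @rdname accessors
setMethod("volData", "LambdaMap", function(object) object@data)
#' @rdname accessors
setMethod("volAffine", "GMVolume", function(object) object@affine)
#' @rdname accessors
setMethod("volAffine", "LambdaMap", function(object) object@affine)
#' @rdname accessors
setMethod("subjectId", "GMVolume", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "LambdaMap", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "WeightedSeries", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "LambdaSeries", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "Scalogram", function(object) object@subjectId)
#' @rdname accessors
setMethod("seriesValues", "WeightedSeries", function(object) object@values)
#' @rdname accessors
setMethod("seriesValues", "LambdaSeries", function(object) object@values)
#' @rdname accessors
setMethod("voxelIndices", "WeightedSeries", function(object) object@voxelIndices)
#' @rdname accessors
setMethod("voxelIndices", "LambdaSeries", function(object) object@voxelIndices)
#' @rdname accessors
setMethod("scalCoeffs", "Scalogram", function(object) object@coeffs)
#' @rdname accessors
setMethod("scalScales", "Scalogram", function(object) object@scales)
#' @rdname accessors
setMethod("boundaryMask", "Scalogram", function(object) object@boundary)

# voxel size as column norms of the 3x3 affine block
.voxdim <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @rdname accessors
setMethod("voxelSize", "GMVolume", function(object) .voxdim(object@affine))
#' @rdname accessors
setMethod("voxelSize", "LambdaMap", function(object) .voxdim(object@affine))

setMethod("show", "GMVolume", function(object) {
  d <- dim(object@data)
  vs <- .voxdim(object@affine)
  cat(sprintf("GMVolume '%s': %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d nonzero\n",
      object@subjectId, d[1], d[2], d[3], vs[1], vs[2], vs[3],
      sum(object@data > 0)))
})

setMethod("show", "WeightedSeries", function(object) {
  cat(sprintf("WeightedSeries '%s': %d points, range [%.4g, %.4g] mm*intensity\n",
      object@subjectId, length(object@values),
      if (length(object@values)) min(object@values) else NA,
      if (length(object@values)) max(object@values) else NA))
})

setMethod("show", "LambdaSeries", function(object) {
  v <- object@values
  cat(sprintf("LambdaSeries '%s': %d points (%d defined), mean lambda %.4g\n",
      object@subjectId, length(v), sum(!is.na(v)), mean(v, na.rm = TRUE)))
})

setMethod("show", "LambdaMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LambdaMap '%s': %d x %d x %d, %d nonzero voxels\n",
      object@subjectId, d[1], d[2], d[3], sum(object@data != 0)))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram '%s': %d points x %d scales (%.3g-%.3g)\n",
      object@subjectId, nrow(object@coeffs), ncol(object@coeffs),
      min(object@scales), max(object@scales)))
})

setMethod("show", "EmbeddingConfig", function(object) {
  cat(sprintf("EmbeddingConfig: m=%d tau=%d theiler=%d tStep=%g maxSteps=%d fit=[%d,%d]\n",
      object@m, object@tau, object@theiler, object@tStep, object@maxSteps,
      object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "WaveletConfig", function(object) {
  cat(sprintf("WaveletConfig: %d scales (%g-%g), omega0=%g, output=%s\n",
      length(object@scales), min(object@scales), max(object@scales),
      object@omega0, object@output))
})
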