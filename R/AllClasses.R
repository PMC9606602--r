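#' @import methods
NULL

#' Gray-matter volume
#'
#' Container for a 3D gray-matter intensity/probability image together with
#' its voxel-to-world affine. Intensities are modulated GM units (arbitrary,
#' non-negative, not restricted to \[0, 1\]); the affine maps *0-based* voxel
#' offsets to world millimetres, following the NIfTI convention, while all
#' voxel indices exposed by this package are 1-based R indices. The world
#' position of voxel \code{(i, j, k)} is therefore
#' \code{affine \%*\% c(i - 1, j - 1, k - 1, 1)}.
#'
#' @slot data 3D numeric array of non-negative, finite intensities.
#' @slot affine 4x4 invertible voxel-to-world transform (mm).
#' @slot subjectId Character scalar identifying the subject.
#'
#' @seealso [GMVolume()], [readGMVolume()], [centerOfMass()]
#' @export
setClass("GMVolume",
  representation(data = "array", affine = "matrix", subjectId = "character"))

setValidity("GMVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (!all(is.finite(d))) return("data must be finite")
  if (any(d < 0)) return("data must be non-negative")
  a <- object@affine
  if (!identical(dim(a), c(4L, 4L))) return("affine must be 4x4")
  if (!all(is.finite(a))) return("affine must be finite")
  if (abs(det(a)) < .Machine$double.eps^0.5) return("affine must be invertible")
  if (length(object@subjectId) != 1L) return("subjectId must be a single string")
  TRUE
})

#' Sorted intensity-weighted distance spatial series
#'
#' The spatial series \eqn{x_i}: the K largest intensity-weighted distances of
#' a [GMVolume], in non-increasing order, with the originating voxel indices
#' retained so per-point quantities can be scattered back into 3D.
#'
#' @slot values Numeric vector, non-increasing, non-negative (mm x intensity).
#' @slot voxelIndices Integer matrix (length(values) x 3) of 1-based voxel
#'   indices, one row per series point, no duplicates.
#' @slot subjectId Character scalar.
#' @seealso [sortAndSelect()], [lambdaLocal()]
#' @export
setClass("WeightedSeries",
  representation(values = "numeric", voxelIndices = "matrix",
                 subjectId = "character"))

setValidity("WeightedSeries", function(object) {
  v <- object@values
  if (!all(is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be non-negative")
  if (is.unsorted(rev(v))) return("values must be non-increasing")
  vi <- object@voxelIndices
  if (!is.numeric(vi) || ncol(vi) != 3L) return("voxelIndices must be an n x 3 matrix")
  if (nrow(vi) != length(v)) return("voxelIndices rows must match length(values)")
  if (anyDuplicated(vi)) return("voxelIndices must be unique")
  TRUE
})

#' Delay-embedding configuration
#'
#' Parameters of the Takens delay embedding and the Rosenstein divergence fit:
#' embedding dimension \code{m}, delay \code{tau} (series steps), Theiler
#' window (minimum index separation in the neighbour search), state-space
#' sampling interval \code{tStep}, the divergence-curve horizon
#' \code{maxSteps} and the step range \code{fitRange} over which the linear
#' region of the mean log-divergence is fitted.
#'
#' @slot m,tau,theiler,maxSteps Integer scalars.
#' @slot tStep Positive numeric scalar (units of one series step).
#' @slot fitRange Integer vector of length 2, \code{start < end <= maxSteps}.
#' @seealso [embeddingConfig()], [lambdaGlobal()]
#' @export
setClass("EmbeddingConfig",
  representation(m = "integer", tau = "integer", theiler = "integer",
                 tStep = "numeric", fitRange = "integer", maxSteps = "integer"))

setValidity("EmbeddingConfig", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@tau < 1L) return("tau must be >= 1")
  if (object@theiler < 0L) return("theiler must be >= 0")
  if (object@tStep <= 0) return("tStep must be positive")
  if (object@maxSteps < 1L) return("maxSteps must be >= 1")
  fr <- object@fitRange
  if (length(fr) != 2L || fr[1L] >= fr[2L]) return("fitRange must be (start, end) with start < end")
  if (fr[2L] > object@maxSteps) return("fitRange end must be <= maxSteps")
  if (fr[1L] < 0L) return("fitRange start must be >= 0")
  TRUE
})

#' Per-point largest-Lyapunov-exponent series
#'
#' Spatially resolved lambda values aligned to the order of the originating
#' [WeightedSeries]; positions where no value is defined (no admissible
#' neighbour, zero initial separation, or past the end of the embedded
#' trajectory) carry \code{NA}.
#'
#' @slot values Numeric vector (1/step units), \code{NA} where undefined.
#' @slot voxelIndices Integer matrix as in [WeightedSeries-class].
#' @slot subjectId Character scalar.
#' @seealso [lambdaLocal()], [lambdaMap()]
#' @export
setClass("LambdaSeries",
  representation(values = "numeric", voxelIndices = "matrix",
                 subjectId = "character"))

setValidity("LambdaSeries", function(object) {
  v <- object@values
  if (any(!is.na(v) & !is.finite(v))) return("values must be finite or NA")
  vi <- object@voxelIndices
  if (!is.numeric(vi) || ncol(vi) != 3L) return("voxelIndices must be an n x 3 matrix")
  if (nrow(vi) != length(v)) return("voxelIndices rows must match length(values)")
  TRUE
})

#' 3D lambda map
#'
#' Lambda values scattered back into the volume grid: nonzero only at voxels
#' that were selected into the top-weighted series (before smoothing).
#'
#' @slot data 3D numeric array; zero outside the selected voxel set.
#' @slot affine 4x4 voxel-to-world transform inherited from the input volume.
#' @slot subjectId Character scalar.
#' @seealso [lambdaMap()], [smoothMap()]
#' @export
setClass("LambdaMap",
  representation(data = "array", affine = "matrix", subjectId = "character"))

setValidity("LambdaMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!all(is.finite(object@data))) return("data must be finite")
  if (!identical(dim(object@affine), c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Continuous-wavelet-transform configuration
#'
#' @slot scales Strictly increasing positive numeric vector of wavelet scales.
#' @slot omega0 Morlet centre frequency (dimensionless).
#' @slot output Either \code{"real"} (signed correlation, the default) or
#'   \code{"modulus"}.
#' @seealso [waveletConfig()], [cwt()]
#' @export
setClass("WaveletConfig",
  representation(scales = "numeric", omega0 = "numeric", output = "character"))

setValidity("WaveletConfig", function(object) {
  s <- object@scales
  if (length(s) < 1L || any(s <= 0)) return("scales must be positive")
  if (is.unsorted(s, strictly = TRUE)) return("scales must be strictly increasing")
  if (object@omega0 <= 0) return("omega0 must be positive")
  if (!object@output %in% c("real", "modulus")) return("output must be 'real' or 'modulus'")
  TRUE
})

#' Scalogram
#'
#' Points-by-scales matrix of continuous-wavelet-transform coefficients of a
#' lambda series (real part by default: signed "correlation" with the Morlet
#' wavelet). Coefficients within one truncated wavelet support of either end
#' of the series are flagged boundary-affected.
#'
#' @slot coeffs Numeric matrix, points x scales.
#' @slot scales Numeric vector, one per column.
#' @slot boundary Logical matrix, same shape; TRUE where the (zero-padded)
#'   boundary can influence the coefficient.
#' @slot subjectId Character scalar.
#' @seealso [cwt()], [scalogramGroupTest()]
#' @export
setClass("Scalogram",
  representation(coeffs = "matrix", scales = "numeric", boundary = "matrix",
                 subjectId = "character"))

setValidity("Scalogram", function(object) {
  if (!all(is.finite(object@coeffs))) return("coeffs must be finite")
  if (ncol(object@coeffs) != length(object@scales)) return("one scale per coefficient column")
  if (!identical(dim(object@coeffs), dim(object@boundary))) return("boundary mask must match coeffs shape")
  TRUE
})
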