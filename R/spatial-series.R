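# World coordinates of 1-based voxel indices through the NIfTI affine
# (which addresses 0-based offsets): world = A %*% [v - 1, 1].
.worldCoords <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3L)
  h <- cbind(idx - 1, 1)
  t(h %*% t(affine))[1:3, , drop = FALSE]
}

#' Intensity-weighted center of mass
#'
#' The gray-level-weighted centroid of the volume: per axis,
#' \eqn{\sum_v w_v i_v / \sum_v w_v} in continuous 1-based voxel coordinates,
#' mapped to world mm through the affine.
#'
#' @param vol A [GMVolume-class] with at least one strictly positive voxel.
#' @return A list with \code{voxel_continuous} (1-based fractional voxel
#'   index, length 3) and \code{world_mm} (length 3).
#' @examples
#' a <- array(0, c(8, 8, 8)); a[4, 5, 6] <- 2
#' centerOfMass(GMVolume(a))$voxel_continuous
#' @export
centerOfMass <- function(vol) {
  w <- vol@data
  tot <- sum(w)
  if (tot <= 0) {
    stop(errorCondition("all-zero volume: center of mass undefined",
                        class = c("chaosgm_empty_volume", "error", "condition")))
  }
  d <- dim(w)
  # marginal sums avoid materialising index grids
  m1 <- rowSums(w)
  m2 <- apply(w, 2L, sum)
  m3 <- colSums(w, dims = 2L)
  vc <- c(sum(m1 * seq_len(d[1])), sum(m2 * seq_len(d[2])),
          sum(m3 * seq_len(d[3]))) / tot
  world <- drop(.worldCoords(vc, vol@affine))
  list(voxel_continuous = vc, world_mm = world)
}

#' Weighted-distance map
#'
#' For every voxel, the Euclidean distance in world mm from the gray-matter
#' center of mass multiplied by the voxel intensity. A voxel of intensity 1 at
#' 3 mm and a voxel of intensity 3 at 1 mm receive the same weighted distance;
#' voxels of zero intensity map to zero.
#'
#' @param vol A [GMVolume-class].
#' @param com Center of mass from [centerOfMass()] on the same volume.
#' @return A 3D numeric array of the same shape as \code{volData(vol)}.
#' @export
weightedDistanceMap <- function(vol, com) {
  d <- dim(vol@data)
  A <- vol@affine
  c0 <- com$world_mm
  # squared world distance expanded over separable per-axis grids:
  # world(v) = A[,1:3] %*% (v-1) + A[,4]; accumulate per-axis outer terms.
  g1 <- seq_len(d[1]) - 1
  g2 <- seq_len(d[2]) - 1
  g3 <- seq_len(d[3]) - 1
  # world components as 3 arrays built from broadcasts
  dist2 <- array(0, d)
  for (ax in 1:3) {
    w <- outer(outer(A[ax, 1] * g1, A[ax, 2] * g2, "+"), A[ax, 3] * g3, "+") +
      (A[ax, 4] - c0[ax])
    dist2 <- dist2 + w * w
  }
  sqrt(dist2) * vol@data
}

#' Sort and select the top-K weighted distances
#'
#' Builds the spatial series: the K largest strictly positive weighted
#' distances in non-increasing order. Ties are broken by ascending linearised
#' (column-major) voxel index, so the output is a deterministic function of
#' the map values and independent of storage order.
#'
#' @param wdMap 3D array from [weightedDistanceMap()].
#' @param K Number of voxels to retain (the analyses here default to 5000 on
#'   full-size GM images).
#' @param subjectId Subject identifier carried into the series.
#' @return A [WeightedSeries-class] of length \code{K}.
#' @export
sortAndSelect <- function(wdMap, K, subjectId = "subject") {
  stopifnot(K >= 1)
  pos <- which(wdMap > 0)
  if (length(pos) < K) {
    stop(errorCondition(
      sprintf("only %d positive voxels, need K=%d", length(pos), K),
      class = c("chaosgm_too_few_voxels", "error", "condition")))
  }
  v <- wdMap[pos]
  ord <- order(-v, pos)[seq_len(K)]
  sel <- pos[ord]
  idx <- arrayInd(sel, dim(wdMap))
  storage.mode(idx) <- "integer"
  new("WeightedSeries", values = as.numeric(v[ord]), voxelIndices = idx,
      subjectId = subjectId)
}

#' Export a weighted series as TSV
#'
#' Columns: rank, i, j, k (1-based voxel indices), weighted_distance.
#'
#' @param series A [WeightedSeries-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSeriesTSV <- function(series, path) {
  vi <- voxelIndices(series)
  df <- data.frame(rank = seq_along(seriesValues(series)),
                   i = vi[, 1], j = vi[, 2], k = vi[, 3],
                   weighted_distance = seriesValues(series))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
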