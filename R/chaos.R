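#' Build an embedding configuration
#'
#' Defaults follow common practice for the Rosenstein largest-Lyapunov
#' estimator on short series: delay \code{tau = 1}, dimension \code{m = 5},
#' Theiler window \code{tau * (m - 1)} (one embedding-window separation),
#' a 50-step divergence horizon and a linear-region fit over steps 1-20.
#' The method itself is robust to moderate changes in \code{m} and \code{tau};
#' [lambdaGrid()] reports the estimate across a grid for diagnostics.
#'
#' @param m Embedding dimension.
#' @param tau Embedding delay, in series steps.
#' @param theiler Minimum index separation for the neighbour search.
#' @param tStep State-space sampling interval (units of one series step):
#'   the divergence-curve abscissa is \code{step * tStep}, so lambda is in
#'   1/\code{tStep} units.
#' @param maxSteps Divergence-curve horizon (steps).
#' @param fitRange Integer (start, end) steps of the linear-region fit.
#' @return An [EmbeddingConfig-class].
#' @export
embeddingConfig <- function(m = 5L, tau = 1L, theiler = tau * (m - 1L),
                            tStep = 1, maxSteps = 50L,
                            fitRange = c(1L, 20L)) {
  new("EmbeddingConfig", m = as.integer(m), tau = as.integer(tau),
      theiler = as.integer(theiler), tStep = as.numeric(tStep),
      maxSteps = as.integer(maxSteps), fitRange = as.integer(fitRange))
}

#' Takens delay embedding
#'
#' Reconstructs the state-space trajectory of a scalar series: row \code{k}
#' (1-based) of the returned matrix is
#' \eqn{(x_k, x_{k+\tau}, \ldots, x_{k+(m-1)\tau})}, giving
#' \eqn{M = N - (m-1)\tau} rows.
#'
#' @param series Numeric vector or [WeightedSeries-class]/[LambdaSeries-class].
#' @param cfg An [EmbeddingConfig-class] (only \code{m} and \code{tau} used).
#' @return An M x m numeric matrix.
#' @examples
#' embedSeries(1:5, embeddingConfig(m = 2, tau = 1, theiler = 0))
#' @export
embedSeries <- function(series, cfg) {
  x <- if (is(series, "WeightedSeries") || is(series, "LambdaSeries"))
    seriesValues(series) else as.numeric(series)
  n <- length(x)
  m <- cfg@m; tau <- cfg@tau
  M <- n - (m - 1L) * tau
  if (M < 2L) {
    stop(errorCondition(
      sprintf("series too short: N=%d gives M=%d rows for m=%d, tau=%d",
              n, M, m, tau),
      class = c("chaosgm_series_too_short", "error", "condition")))
  }
  out <- matrix(0, M, m)
  for (col in seq_len(m)) {
    out[, col] <- x[seq.int(1L + (col - 1L) * tau, length.out = M)]
  }
  out
}

#' Nearest neighbours under a Theiler window
#'
#' For each trajectory row \code{k}, the index \code{j} minimising the
#' Euclidean state-space distance subject to \code{|k - j| > theiler}; ties
#' are broken by the smaller \code{j}. Rows with no admissible candidate are
#' returned as \code{NA}.
#'
#' @param traj M x m trajectory matrix from [embedSeries()].
#' @param theiler Non-negative integer exclusion window.
#' @return Integer vector of length M (with \code{NA} flags).
#' @export
nearestNeighbors <- function(traj, theiler = 0L) {
  M <- nrow(traj)
  stopifnot(M >= 2L)
  theiler <- as.integer(theiler)
  nn <- rep(NA_integer_, M)
  if (theiler >= M - 1L) return(nn)
  chunk <- max(1L, min(M, floor(2e6 / M)))
  j <- seq_len(M)
  for (start in seq.int(1L, M, by = chunk)) {
    ks <- start:min(M, start + chunk - 1L)
    D2 <- matrix(0, length(ks), M)
    for (ax in seq_len(ncol(traj))) {
      D2 <- D2 + outer(traj[ks, ax], traj[, ax], "-")^2
    }
    # Theiler band exclusion (includes j == k)
    excl <- abs(outer(ks, j, "-")) <= theiler
    D2[excl] <- Inf
    nn[ks] <- max.col(-D2, ties.method = "first")
  }
  nn
}

#' Per-reference log-divergence trajectories
#'
#' For each reference row \code{k} with neighbour \code{j}, the natural log of
#' the state-space distance between \eqn{X_{k+s}} and \eqn{X_{j+s}} for
#' \code{s = 0..maxSteps}. Entries are \code{NA} where the pair runs off the
#' trajectory, the reference has no admissible neighbour, or the distance is
#' exactly zero (log undefined; such pairs are excluded per step rather than
#' jittered).
#'
#' @param traj Trajectory matrix.
#' @param neighbors Integer vector from [nearestNeighbors()].
#' @param maxSteps Horizon in steps.
#' @return M x (maxSteps + 1) matrix of log-distances; column \code{s + 1}
#'   holds step \code{s}.
#' @export
logDivergence <- function(traj, neighbors, maxSteps) {
  M <- nrow(traj)
  out <- matrix(NA_real_, M, maxSteps + 1L)
  ref <- which(!is.na(neighbors))
  for (s in 0:maxSteps) {
    ok <- ref[ref + s <= M & neighbors[ref] + s <= M]
    if (!length(ok)) break
    diff <- traj[ok + s, , drop = FALSE] - traj[neighbors[ok] + s, , drop = FALSE]
    d2 <- rowSums(diff * diff)
    ld <- ifelse(d2 > 0, 0.5 * log(d2), NA_real_)
    out[ok, s + 1L] <- ld
  }
  out
}

#' Average divergence curve
#'
#' The Rosenstein divergence curve: for each step \code{s}, the mean over
#' reference points of the log-distance between the image of each point and
#' the image of its nearest neighbour, \eqn{\langle \ln d(s) \rangle}. Under
#' exponential separation \eqn{d(s) = d(0) e^{\lambda_1 s}} this curve is
#' linear in \code{s} with slope \eqn{\lambda_1}.
#'
#' @param traj Trajectory matrix.
#' @param neighbors From [nearestNeighbors()].
#' @param cfg An [EmbeddingConfig-class] (\code{maxSteps} used).
#' @return data.frame with columns \code{step}, \code{mean_log_div},
#'   \code{count} (contributing pairs; zero-distance pairs are excluded and
#'   reduce the count).
#' @export
divergenceCurve <- function(traj, neighbors, cfg) {
  ld <- logDivergence(traj, neighbors, cfg@maxSteps)
  count <- colSums(!is.na(ld))
  if (count[1L] == 0L) {
    stop(errorCondition("no valid neighbour pairs at step 0",
                        class = c("chaosgm_degenerate_divergence", "error", "condition")))
  }
  mld <- suppressWarnings(colMeans(ld, na.rm = TRUE))
  mld[count == 0L] <- NA_real_
  data.frame(step = 0:cfg@maxSteps, mean_log_div = mld, count = count)
}

#' Global largest Lyapunov exponent
#'
#' Least-squares slope of the mean log-divergence against \code{step * tStep}
#' over the configured fit range; the slope is the global lambda (units
#' 1/\code{tStep}).
#'
#' @param curve data.frame from [divergenceCurve()].
#' @param cfg An [EmbeddingConfig-class] (\code{fitRange}, \code{tStep}).
#' @return List: \code{lambda_global}, \code{intercept}, \code{fit_r2},
#'   \code{n_fit}.
#' @export
lambdaGlobal <- function(curve, cfg) {
  sel <- curve$step >= cfg@fitRange[1L] & curve$step <= cfg@fitRange[2L] &
    curve$count > 0 & is.finite(curve$mean_log_div)
  if (sum(sel) < 2L) {
    stop(errorCondition("fewer than 2 usable points in fit range",
                        class = c("chaosgm_degenerate_fit", "error", "condition")))
  }
  x <- curve$step[sel] * cfg@tStep
  y <- curve$mean_log_div[sel]
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  ssres <- sum((y - intercept - slope * x)^2)
  sstot <- sum((y - ym)^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else 1
  list(lambda_global = slope, intercept = intercept,
       fit_r2 = max(0, min(1, r2)), n_fit = sum(sel))
}

#' Spatially resolved lambda series
#'
#' Per-reference-point lambda, aligned back to the positions (and voxels) of
#' the originating series. Two localization rules are provided:
#' \describe{
#'   \item{\code{"slope"} (default)}{the least-squares slope of the
#'     reference's own log-divergence \eqn{\ln d_k(s)} against
#'     \eqn{s \cdot T} over the configured fit range — the per-reference
#'     analogue of the global estimator (which fits the *mean* curve), so the
#'     mean of local values recovers the global lambda on linear curves.}
#'   \item{\code{"difference"}}{the one-step finite difference
#'     \eqn{\lambda_1(k) = (\ln d_k(1) - \ln d_k(0)) / T}. This uses two
#'     steps only and is accordingly much noisier; it is retained as the
#'     minimal literal localization of the divergence relation.}
#' }
#' Positions beyond the embedded trajectory, references without an admissible
#' neighbour, and references with fewer than two usable steps are \code{NA}.
#'
#' @param logDiv Matrix from [logDivergence()].
#' @param cfg An [EmbeddingConfig-class] (\code{tStep}; \code{fitRange} for
#'   the slope rule).
#' @param series The originating [WeightedSeries-class] (for length and voxel
#'   bookkeeping); optional — if omitted a bare numeric vector is returned.
#' @param method Localization rule, \code{"slope"} or \code{"difference"}.
#' @return A [LambdaSeries-class] (or numeric vector) of the same length as
#'   the input series.
#' @export
lambdaLocal <- function(logDiv, cfg, series = NULL,
                        method = c("slope", "difference")) {
  method <- match.arg(method)
  M <- nrow(logDiv)
  if (method == "difference") {
    lam <- (logDiv[, 2L] - logDiv[, 1L]) / cfg@tStep
  } else {
    cols <- (cfg@fitRange[1L]:cfg@fitRange[2L]) + 1L
    cols <- cols[cols <= ncol(logDiv)]
    sub <- logDiv[, cols, drop = FALSE]
    steps <- matrix((cols - 1L) * cfg@tStep, M, length(cols), byrow = TRUE)
    W <- !is.na(sub)
    sub0 <- ifelse(W, sub, 0)
    sx <- rowSums(steps * W); sy <- rowSums(sub0)
    sxx <- rowSums(steps^2 * W); sxy <- rowSums(steps * sub0)
    nk <- rowSums(W)
    den <- nk * sxx - sx^2
    lam <- ifelse(nk >= 2 & den > 0, (nk * sxy - sx * sy) / den, NA_real_)
  }
  if (is.null(series)) return(lam)
  n <- length(seriesValues(series))
  vals <- rep(NA_real_, n)
  vals[seq_len(M)] <- lam
  new("LambdaSeries", values = vals, voxelIndices = voxelIndices(series),
      subjectId = subjectId(series))
}

#' Scatter a lambda series into a 3D map
#'
#' Writes each defined lambda value at its originating voxel; all other
#' voxels (including flagged-missing series positions, whose count is
#' reported via a message) are zero.
#'
#' @param ls A [LambdaSeries-class].
#' @param shape Integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @return A [LambdaMap-class].
#' @export
lambdaMap <- function(ls, shape, affine) {
  vi <- voxelIndices(ls)
  if (nrow(vi) && (any(vi < 1L) || any(vi > matrix(shape, nrow(vi), 3, byrow = TRUE)))) {
    stop(errorCondition("voxel index out of bounds for given shape",
                        class = c("chaosgm_index_out_of_bounds", "error", "condition")))
  }
  arr <- array(0, shape)
  v <- seriesValues(ls)
  nmiss <- sum(is.na(v))
  if (nmiss > 0) {
    message(sprintf("lambdaMap: %d flagged-missing lambda value(s) written as 0", nmiss))
    v[is.na(v)] <- 0
  }
  if (nrow(vi)) arr[vi] <- v
  new("LambdaMap", data = arr, affine = affine, subjectId = subjectId(ls))
}

# normalized 1D Gaussian kernel for sigma in voxel units
.gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  t <- (-r):r
  k <- exp(-t^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# zero-padded convolution along one axis via a banded matrix product
.convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    jj <- (i - r):(i + r)
    ok <- jj >= 1L & jj <= n
    K[i, jj[ok]] <- kernel[ok]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  m <- matrix(ap, nrow = n)
  res <- K %*% m
  dim(res) <- d[perm]
  aperm(res, order(perm))
}

#' Gaussian smoothing of a lambda map
#'
#' Separable Gaussian convolution with per-axis sigma
#' \code{fwhm / (voxel_size * sqrt(8 log 2))} (FWHM stated in mm, the
#' neuroimaging convention), zero-padded at the boundary so the total map sum
#' is preserved up to boundary loss.
#'
#' @param map A [LambdaMap-class].
#' @param fwhm FWHM in mm, scalar or length-3 (default 8 mm isotropic).
#' @return A smoothed [LambdaMap-class].
#' @export
smoothMap <- function(map, fwhm = 8) {
  fwhm <- rep_len(fwhm, 3L)
  if (any(fwhm <= 0)) {
    stop(errorCondition("fwhm must be positive",
                        class = c("chaosgm_bad_fwhm", "error", "condition")))
  }
  vs <- .voxdim(map@affine)
  sigma <- fwhm / (vs * sqrt(8 * log(2)))
  arr <- map@data
  for (ax in 1:3) {
    arr <- .convolveAxis(arr, .gaussKernel1d(sigma[ax]), ax)
  }
  new("LambdaMap", data = arr, affine = map@affine, subjectId = map@subjectId)
}

#' Lambda estimates across an (m, tau) grid
#'
#' Diagnostic sweep: runs the full Rosenstein estimate for every combination
#' of the supplied embedding dimensions and delays.
#'
#' @param series Numeric vector or [WeightedSeries-class].
#' @param ms,taus Integer vectors of embedding dimensions and delays.
#' @param cfg Template [EmbeddingConfig-class] supplying the remaining
#'   parameters (Theiler window is re-derived as \code{tau * (m - 1)}).
#' @return data.frame with columns m, tau, lambda_global, fit_r2.
#' @export
lambdaGrid <- function(series, ms = 2:6, taus = 1:2, cfg = embeddingConfig()) {
  rows <- expand.grid(m = as.integer(ms), tau = as.integer(taus))
  res <- lapply(seq_len(nrow(rows)), function(i) {
    ci <- embeddingConfig(m = rows$m[i], tau = rows$tau[i],
                          tStep = cfg@tStep, maxSteps = cfg@maxSteps,
                          fitRange = cfg@fitRange)
    traj <- embedSeries(series, ci)
    nn <- nearestNeighbors(traj, ci@theiler)
    est <- lambdaGlobal(divergenceCurve(traj, nn, ci), ci)
    c(lambda_global = est$lambda_global, fit_r2 = est$fit_r2)
  })
  cbind(rows, do.call(rbind, res))
}
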