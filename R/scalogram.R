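#' Build a wavelet configuration
#'
#' Defaults: integer scales 1..100 and Morlet centre frequency
#' \code{omega0 = 6}, the standard admissible choice for which the wavelet's
#' zero-mean correction is negligible. The coefficient stored per cell is the
#' real part of the complex coefficient — a signed "correlation" with the
#' wavelet (positive and negative matches) — unless \code{output =
#' "modulus"}.
#'
#' @param scales Strictly increasing positive numeric vector.
#' @param omega0 Morlet centre frequency (dimensionless).
#' @param output \code{"real"} or \code{"modulus"}.
#' @return A [WaveletConfig-class].
#' @export
waveletConfig <- function(scales = 1:100, omega0 = 6, output = "real") {
  new("WaveletConfig", scales = as.numeric(scales), omega0 = as.numeric(omega0),
      output = output)
}

# truncated support radius, in points, of the scaled wavelet
.morletRadius <- function(scale) ceiling(8 * scale)

#' Sampled complex Morlet wavelet
#'
#' \deqn{\psi_s(t) = s^{-1/2} \pi^{-1/4} e^{i \omega_0 t / s}
#'   e^{-(t/s)^2 / 2}}
#' sampled at the integer offsets of \code{grid}, with support truncated to
#' \eqn{|t/s| \le 8} (the Gaussian envelope is below 1e-14 beyond that, so
#' the truncation error of the unit L2 norm is far below single precision).
#'
#' @param scale Positive scale.
#' @param grid Integer offsets at which to sample (default: the full
#'   truncated support).
#' @param cfg A [WaveletConfig-class] (\code{omega0} used).
#' @return Complex vector along \code{grid}.
#' @export
morletWavelet <- function(scale, grid = NULL, cfg = waveletConfig()) {
  if (scale <= 0) {
    stop(errorCondition("scale must be positive",
                        class = c("chaosgm_bad_scale", "error", "condition")))
  }
  if (is.null(grid)) {
    r <- .morletRadius(scale)
    grid <- (-r):r
  }
  u <- grid / scale
  psi <- scale^(-0.5) * pi^(-0.25) * exp(1i * cfg@omega0 * u - u^2 / 2)
  psi[abs(u) > 8] <- 0 + 0i
  psi
}

#' Continuous wavelet transform of a lambda series
#'
#' For each point \code{p} and scale \code{s}, the correlation of the series
#' with the scaled Morlet wavelet centred at \code{p}:
#' \eqn{c_{p,s} = \sum_t x_t \overline{\psi_s(t - p)}}, with zero-padded
#' boundaries. Missing series values are imputed as 0 (their count is
#' reported). Computed by FFT convolution on a common padded length, which is
#' exact (to rounding) for the truncated kernels.
#'
#' @param series A [LambdaSeries-class], [WeightedSeries-class] or numeric
#'   vector (may contain \code{NA}).
#' @param cfg A [WaveletConfig-class].
#' @return A [Scalogram-class]; cells within one truncated support radius of
#'   either series end are flagged in its boundary mask.
#' @export
cwt <- function(series, cfg = waveletConfig()) {
  sid <- if (is.numeric(series)) "series" else subjectId(series)
  x <- if (is.numeric(series)) as.numeric(series) else seriesValues(series)
  n <- length(x)
  if (n < 2L) {
    stop(errorCondition("series must have length >= 2",
                        class = c("chaosgm_empty_series", "error", "condition")))
  }
  nmiss <- sum(is.na(x))
  if (nmiss > 0) {
    message(sprintf("cwt: %d missing value(s) imputed as 0", nmiss))
    x[is.na(x)] <- 0
  }
  scales <- cfg@scales
  rmax <- .morletRadius(max(scales))
  L <- stats::nextn(n + 2L * rmax + 1L, 2L)
  fx <- stats::fft(c(x, rep(0, L - n)))
  coeffs <- matrix(0, n, length(scales))
  bound <- matrix(FALSE, n, length(scales))
  p <- seq_len(n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    r <- .morletRadius(s)
    psi <- morletWavelet(s, (-r):r, cfg)
    # cross-correlation as circular convolution with g[v] = conj(psi(-v))
    g <- Conj(rev(psi))           # g[v] for v = -r..r, reversed => index v
    gp <- complex(length.out = L)
    gp[1:(r + 1L)] <- g[(r + 1L):(2L * r + 1L)]      # v = 0..r
    gp[(L - r + 1L):L] <- g[1:r]                     # v = -r..-1
    cc <- stats::fft(fx * stats::fft(gp), inverse = TRUE) / L
    vals <- cc[p]
    coeffs[, si] <- if (cfg@output == "modulus") Mod(vals) else Re(vals)
    bound[, si] <- (p - 1L) < r | (n - p) < r
  }
  new("Scalogram", coeffs = coeffs, scales = scales, boundary = bound,
      subjectId = sid)
}

#' Scalograms for a cohort
#'
#' One [cwt()] per subject; all series must have the same length so the
#' scalograms share a common shape for cell-wise group tests.
#'
#' @param seriesList List of [LambdaSeries-class] (or numeric vectors).
#' @param cfg A [WaveletConfig-class].
#' @return List of [Scalogram-class], in input order.
#' @export
cohortScalograms <- function(seriesList, cfg = waveletConfig()) {
  lens <- vapply(seriesList, function(s)
    length(if (is.numeric(s)) s else seriesValues(s)), integer(1))
  if (length(unique(lens)) > 1L) {
    stop(errorCondition("all series must have the same length",
                        class = c("chaosgm_length_mismatch", "error", "condition")))
  }
  lapply(seriesList, cwt, cfg = cfg)
}

#' Write a scalogram to TSV
#'
#' Plain-text matrix, one row per series point, one column per scale
#' (header \code{scale_<s>}).
#'
#' @param scal A [Scalogram-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeScalogramTSV <- function(scal, path) {
  m <- scalCoeffs(scal)
  colnames(m) <- paste0("scale_", scalScales(scal))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
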