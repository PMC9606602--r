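#' Phantom configuration
#'
#' Parameters of the corrugated-shell gray-matter phantom: a spherical shell
#' of Gaussian radial profile whose radius is modulated over angle by
#' band-limited unit-variance angular noise,
#' \deqn{I(v) = \exp\{-(r_v - R(u_v))^2 / 2 w^2\}, \quad
#'   R(u) = r_0 (1 + a B(u)),}
#' plus non-negative truncated Gaussian intensity noise. The corrugation
#' amplitude \code{a} is the surface-complexity handle that differs between
#' synthetic groups, mimicking cortical-folding differences.
#'
#' The corrugation field emulates *spatially normalised* cohorts (the method
#' consumes modulated warped GM maps, in which anatomy is aligned to a common
#' template): \eqn{B = \sqrt{1 - w^2} B_{tmpl} + w B_{subj}}, a shared
#' template field (seeded by \code{template_seed}, common to a cohort) plus a
#' subject-specific field (seeded by \code{seed}) carrying fraction
#' \code{subject_frac} of the corrugation SD.
#'
#' @param shape Grid dimensions (default 64^3).
#' @param voxel_mm Isotropic voxel size in mm (default 1.5, matching typical
#'   normalised GM maps).
#' @param r0 Mean shell radius in mm; default 22% of the smallest grid
#'   extent, which leaves room for strong corrugation within the grid.
#' @param shell_width Radial Gaussian width in mm.
#' @param corrugation_amp Dimensionless corrugation amplitude \code{a >= 0}.
#' @param corrugation_freq Band limit (highest angular wavenumber) of the
#'   corrugation field.
#' @param noise_sd Intensity noise SD (truncated at 0).
#' @param seed Integer seed for the subject-specific field and intensity
#'   noise; phantoms are bit-reproducible given the config.
#' @param template_seed Integer seed of the shared template field.
#' @param subject_frac Fraction of the corrugation SD that is
#'   subject-specific (0 = identical anatomy, 1 = fully idiosyncratic).
#' @return List of class \code{chaosgm_phantom_cfg}.
#' @export
phantomConfig <- function(shape = c(64L, 64L, 64L), voxel_mm = 1.5, r0 = NULL,
                          shell_width = 3, corrugation_amp = 0.05,
                          corrugation_freq = 6L, noise_sd = 0.02, seed = 1L,
                          template_seed = 1000L, subject_frac = 0.3) {
  shape <- as.integer(rep_len(shape, 3L))
  extent <- min(shape) * voxel_mm
  if (is.null(r0)) r0 <- 0.22 * extent
  cfg <- list(shape = shape, voxel_mm = voxel_mm, r0 = r0,
              shell_width = shell_width, corrugation_amp = corrugation_amp,
              corrugation_freq = as.integer(corrugation_freq),
              noise_sd = noise_sd, seed = as.integer(seed),
              template_seed = as.integer(template_seed),
              subject_frac = subject_frac)
  stopifnot(voxel_mm > 0, r0 > 0, shell_width > 0, corrugation_amp >= 0,
            cfg$corrugation_freq >= 1L, noise_sd >= 0,
            subject_frac >= 0, subject_frac <= 1)
  # |B| rarely exceeds ~4 SD; require the corrugated shell plus 3 radial
  # widths to stay inside the half-extent
  if (r0 * (1 + 4 * corrugation_amp) + 3 * shell_width > extent / 2) {
    stop(errorCondition("shell (with corrugation) exceeds the grid",
                        class = c("chaosgm_shell_too_big", "error", "condition")))
  }
  class(cfg) <- "chaosgm_phantom_cfg"
  cfg
}

# deterministic quasi-uniform directions on the sphere (Fibonacci lattice),
# used to normalise the corrugation field to unit variance
.fibonacciSphere <- function(n = 2048L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# draws one band-limited field's parameters from the seeded generator and
# returns a closure evaluating the normalised field at unit vectors (rows)
.corrugationField <- function(freq, seed) {
  set.seed(seed)
  J <- 2L * freq
  k <- sample(seq_len(freq), J, replace = TRUE)     # angular wavenumbers
  dirs <- matrix(stats::rnorm(3L * J), J, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amp <- stats::rnorm(J)
  phase <- stats::runif(J, 0, 2 * pi)
  raw <- function(U) {
    acc <- numeric(nrow(U))
    proj <- U %*% t(dirs)                           # n x J
    for (j in seq_len(J)) {
      acc <- acc + amp[j] * cos(pi * k[j] * proj[, j] + phase[j])
    }
    acc
  }
  ref <- raw(.fibonacciSphere())
  mu <- mean(ref); sdv <- stats::sd(ref)
  if (sdv == 0) sdv <- 1
  function(U) (raw(U) - mu) / sdv
}

# template + subject mixture, unit variance overall
.phantomField <- function(cfg) {
  w <- cfg$subject_frac
  Bt <- .corrugationField(cfg$corrugation_freq, cfg$template_seed)
  Bs <- .corrugationField(cfg$corrugation_freq, cfg$seed)
  function(U) sqrt(1 - w^2) * Bt(U) + w * Bs(U)
}

#' Generate a corrugated-shell phantom volume
#'
#' Deterministic given its config (the seed drives both the corrugation
#' field and the intensity noise). With zero corrugation and zero noise the
#' phantom is a perfect spherical shell centred on the grid centre.
#'
#' @param cfg A [phantomConfig()].
#' @param subjectId Subject identifier.
#' @return A [GMVolume-class] with affine \code{diag(voxel_mm)} (world origin
#'   at the first voxel).
#' @export
makePhantom <- function(cfg, subjectId = "phantom") {
  d <- cfg$shape
  ctr <- (d + 1) / 2                                # grid centre, 1-based
  g1 <- (seq_len(d[1]) - ctr[1]) * cfg$voxel_mm
  g2 <- (seq_len(d[2]) - ctr[2]) * cfg$voxel_mm
  g3 <- (seq_len(d[3]) - ctr[3]) * cfg$voxel_mm
  X <- array(g1, d)
  Y <- array(rep(g2, each = d[1]), d)
  Z <- array(rep(g3, each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  B <- .phantomField(cfg)
  u <- cbind(as.numeric(X), as.numeric(Y), as.numeric(Z))
  rn <- pmax(as.numeric(r), .Machine$double.eps)
  u <- u / rn
  Rang <- cfg$r0 * (1 + cfg$corrugation_amp * B(u))
  inten <- exp(-(as.numeric(r) - Rang)^2 / (2 * cfg$shell_width^2))
  if (cfg$noise_sd > 0) {
    # noise stream re-seeded from the subject seed (offset to decouple it
    # from the subject field draw)
    set.seed((cfg$seed + 7L) %% 2147483629L)
    inten <- inten + pmax(stats::rnorm(length(inten), 0, cfg$noise_sd), 0)
  }
  arr <- array(inten, d)
  aff <- diag(c(rep(cfg$voxel_mm, 3), 1))
  GMVolume(arr, aff, subjectId)
}

#' Shell radius over angle
#'
#' The corrugated radius \eqn{R(u)} evaluated on a deterministic
#' quasi-uniform sphere sample — the phantom's surface-roughness profile.
#' Its variance grows as \eqn{(r_0 a)^2} for a fixed seed, giving a strictly
#' monotone surface-complexity handle.
#'
#' @param cfg A [phantomConfig()].
#' @param n Number of sphere directions.
#' @return Numeric vector of radii (mm).
#' @export
phantomRadiusProfile <- function(cfg, n = 2048L) {
  B <- .phantomField(cfg)
  cfg$r0 * (1 + cfg$corrugation_amp * B(.fibonacciSphere(n)))
}

# deterministic per-subject seed derived from a master seed (kept < 2^31)
.subjectSeed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 9973) %% 2147483629)
}

#' Cohort configuration
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_effect Additive shift of the corrugation amplitude for group
#'   B (group A keeps the phantom config's amplitude).
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return List of class \code{chaosgm_cohort_cfg}.
#' @export
cohortConfig <- function(n_per_group = 8L, group_effect = 0, seed = 1L) {
  stopifnot(n_per_group >= 2L)
  structure(list(n_per_group = as.integer(n_per_group),
                 group_effect = group_effect, seed = as.integer(seed)),
            class = "chaosgm_cohort_cfg")
}

#' Generate a two-group phantom cohort
#'
#' \code{n_per_group} phantoms per group with per-subject seeds derived from
#' the master seed; group B's corrugation amplitude is group A's plus
#' \code{group_effect}. Covariates (age, sex, education years, smoking,
#' alcohol) are sampled independently of group, so they are null nuisance
#' variables unless the generator is extended.
#'
#' @param cfg A [cohortConfig()].
#' @param phantomCfg Template [phantomConfig()]; its \code{seed} is replaced
#'   per subject, and \code{corrugation_amp} shifted for group B.
#' @return List with \code{volumes} (list of [GMVolume-class]) and
#'   \code{covariates} (data.frame with subject_id, group, age, sex,
#'   education, smoking, alcohol), rows aligned with \code{volumes}.
#' @export
makeCohort <- function(cfg, phantomCfg = phantomConfig()) {
  n <- cfg$n_per_group
  ids <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  grp <- rep(c("A", "B"), each = n)
  set.seed(cfg$seed)
  cov <- data.frame(
    subject_id = ids,
    group = factor(grp),
    age = round(stats::runif(2 * n, 20, 40), 1),
    sex = stats::rbinom(2 * n, 1, 0.5),
    education = round(stats::rnorm(2 * n, 13, 2), 1),
    smoking = round(pmax(stats::rnorm(2 * n, 5, 3), 0), 1),
    alcohol = stats::rbinom(2 * n, 1, 0.4)
  )
  vols <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    ci <- phantomCfg
    ci$seed <- .subjectSeed(cfg$seed, i)
    # cohort-level template anatomy derived from the master seed
    ci$template_seed <- .subjectSeed(cfg$seed, 0L)
    if (grp[i] == "B") ci$corrugation_amp <- ci$corrugation_amp + cfg$group_effect
    # re-validate the shifted amplitude against the grid
    ci <- phantomConfig(shape = ci$shape, voxel_mm = ci$voxel_mm, r0 = ci$r0,
                        shell_width = ci$shell_width,
                        corrugation_amp = ci$corrugation_amp,
                        corrugation_freq = ci$corrugation_freq,
                        noise_sd = ci$noise_sd, seed = ci$seed,
                        template_seed = ci$template_seed,
                        subject_frac = ci$subject_frac)
    vols[[i]] <- makePhantom(ci, subjectId = ids[i])
  }
  list(volumes = vols, covariates = cov)
}
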