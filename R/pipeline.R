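# re-raises stage errors with a stage tag while keeping the original class
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                        class = unique(c(class(e)[1L], "chaosgm_stage_error",
                                         "error", "condition"))))
  })
}

#' Run the single-subject analysis chain
#'
#' Executes, in order: intensity-weighted centre of mass, weighted-distance
#' map, top-K sort/selection, delay embedding, Rosenstein nearest-neighbour
#' divergence, global and per-point lambda, 3D lambda map and Gaussian
#' smoothing, and the Morlet scalogram of the lambda series. Errors are
#' re-raised with a stage tag. The run is fully deterministic (no RNG).
#'
#' @param vol A [GMVolume-class].
#' @param K Number of top-weighted voxels to retain.
#' @param embedCfg An [EmbeddingConfig-class].
#' @param waveCfg A [WaveletConfig-class].
#' @param fwhm Smoothing FWHM in mm.
#' @param outDir Optional directory; when given, the series (TSV), divergence
#'   curve (TSV), lambda maps (NIfTI) and scalogram (TSV) are persisted.
#' @return List: \code{com}, \code{series}, \code{curve}, \code{global}
#'   (lambda fit), \code{lambda_series}, \code{lambda_map},
#'   \code{smoothed_map}, \code{scalogram}, \code{counts}.
#' @export
runSubject <- function(vol, K = 5000L, embedCfg = embeddingConfig(),
                       waveCfg = waveletConfig(), fwhm = 8, outDir = NULL) {
  sid <- subjectId(vol)
  com <- .stage("center_of_mass", centerOfMass(vol))
  wd <- .stage("weighted_distance", weightedDistanceMap(vol, com))
  series <- .stage("sort_select", sortAndSelect(wd, K, subjectId = sid))
  traj <- .stage("embed", embedSeries(series, embedCfg))
  nn <- .stage("neighbors", nearestNeighbors(traj, embedCfg@theiler))
  ld <- .stage("divergence", logDivergence(traj, nn, embedCfg@maxSteps))
  curve <- .stage("divergence", {
    count <- colSums(!is.na(ld))
    if (count[1L] == 0L)
      stop(errorCondition("no valid neighbour pairs at step 0",
                          class = c("chaosgm_degenerate_divergence", "error",
                                    "condition")))
    mld <- suppressWarnings(colMeans(ld, na.rm = TRUE))
    mld[count == 0L] <- NA_real_
    data.frame(step = 0:embedCfg@maxSteps, mean_log_div = mld, count = count)
  })
  glob <- .stage("lambda_global", lambdaGlobal(curve, embedCfg))
  lser <- .stage("lambda_local", lambdaLocal(ld, embedCfg, series))
  lmap <- .stage("lambda_map",
                 suppressMessages(lambdaMap(lser, dim(volData(vol)), volAffine(vol))))
  smap <- .stage("smooth", smoothMap(lmap, fwhm))
  scal <- .stage("scalogram", suppressMessages(cwt(lser, waveCfg)))
  counts <- list(n_series = length(seriesValues(series)),
                 n_lambda_defined = sum(!is.na(seriesValues(lser))),
                 n_lambda_missing = sum(is.na(seriesValues(lser))),
                 n_boundary_cells = sum(boundaryMask(scal)))
  message(sprintf("subject %s: K=%d, lambda=%.4g (r2=%.3f), %d/%d lambda defined",
                  sid, K, glob$lambda_global, glob$fit_r2,
                  counts$n_lambda_defined, counts$n_series))
  out <- list(com = com, series = series, curve = curve, global = glob,
              lambda_series = lser, lambda_map = lmap, smoothed_map = smap,
              scalogram = scal, counts = counts)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSeriesTSV(series, file.path(outDir, paste0(sid, "_series.tsv")))
    utils::write.table(curve, file.path(outDir, paste0(sid, "_divergence.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeVolume(lmap, file.path(outDir, paste0(sid, "_lambda.nii.gz")))
    writeVolume(smap, file.path(outDir, paste0(sid, "_lambda_s", fwhm, ".nii.gz")))
    writeScalogramTSV(scal, file.path(outDir, paste0(sid, "_scalogram.tsv")))
  }
  out
}

#' Run the full group analysis
#'
#' Validates inputs first (covariate columns, group sizes, consistent volume
#' shapes), runs [runSubject()] for every volume, then compares groups:
#' covariate-adjusted voxel-wise GLM and permutation maxT FWE on the smoothed
#' lambda maps, and the cell-wise FDR-controlled scalogram test. Writes a
#' machine-readable manifest (all parameters and seeds; no timestamps, so
#' identical runs produce identical manifests) when \code{outDir} is given.
#'
#' @param volumes List of [GMVolume-class], aligned with \code{table} rows.
#' @param table Covariate table with \code{subject_id} and two-level
#'   \code{group}.
#' @param covariateNames Covariate columns used for adjustment.
#' @param K,embedCfg,waveCfg,fwhm Per-subject parameters (see
#'   [runSubject()]).
#' @param nPerm,permSeed,cdtP,extent Permutation-FWE parameters.
#' @param q Scalogram FDR level.
#' @param minCoverage Minimum per-subject smoothed selection coverage for a
#'   voxel to enter the voxel-wise analyses (see [coverageMask()]).
#' @param atlas Optional integer-labelled atlas array for region means of the
#'   cohort-mean lambda map.
#' @param outDir Optional output directory.
#' @return List: \code{subjects} (per-subject results), \code{glm},
#'   \code{fwe}, \code{scaletest}, \code{region_means} (or NULL),
#'   \code{manifest}.
#' @export
runGroup <- function(volumes, table, covariateNames = character(),
                     K = 5000L, embedCfg = embeddingConfig(),
                     waveCfg = waveletConfig(), fwhm = 8,
                     nPerm = 1000L, permSeed = 1L, cdtP = 0.001,
                     extent = 10L, q = 0.05, minCoverage = 0.001,
                     atlas = NULL, outDir = NULL) {
  .stage("validate", {
    stopifnot(length(volumes) == nrow(table))
    .designMatrix(table, covariateNames)
    shapes <- vapply(volumes, function(v) paste(dim(volData(v)), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) > 1L)
      stop(errorCondition("inconsistent volume shapes across subjects",
                          class = c("chaosgm_shape_mismatch", "error", "condition")))
  })
  subjects <- lapply(volumes, runSubject, K = K, embedCfg = embedCfg,
                     waveCfg = waveCfg, fwhm = fwhm,
                     outDir = if (is.null(outDir)) NULL else file.path(outDir, "subjects"))
  smoothed <- lapply(subjects, `[[`, "smoothed_map")
  cmask <- .stage("mask", coverageMask(lapply(subjects, `[[`, "lambda_map"),
                                       fwhm = fwhm, minCoverage = minCoverage))
  glm <- .stage("glm", glmContrast(smoothed, table, covariateNames,
                                   mask = cmask))
  fwe <- .stage("fwe", permutationFWE(smoothed, table, covariateNames,
                                      nPerm = nPerm, seed = permSeed,
                                      cdtP = cdtP, extent = extent,
                                      mask = cmask))
  grp <- droplevels(factor(table$group))
  scals <- lapply(subjects, `[[`, "scalogram")
  scaletest <- .stage("scaletest",
    scalogramGroupTest(scals[grp == levels(grp)[1L]],
                       scals[grp == levels(grp)[2L]], q = q))
  rmeans <- NULL
  if (!is.null(atlas)) {
    meanMap <- Reduce(`+`, lapply(subjects, function(s) volData(s$lambda_map))) /
      length(subjects)
    rmeans <- .stage("region_means",
      regionMeans(new("LambdaMap", data = meanMap,
                      affine = volAffine(volumes[[1]]), subjectId = "mean"),
                  atlas))
  }
  manifest <- list(
    package = "chaosgm",
    version = as.character(utils::packageVersion("chaosgm")),
    n_subjects = length(volumes),
    groups = as.list(table(grp)),
    parameters = list(K = K, m = embedCfg@m, tau = embedCfg@tau,
                      theiler = embedCfg@theiler, t_step = embedCfg@tStep,
                      max_steps = embedCfg@maxSteps,
                      fit_range = embedCfg@fitRange, fwhm = fwhm,
                      scales = range(waveCfg@scales), omega0 = waveCfg@omega0,
                      covariates = covariateNames, n_perm = nPerm,
                      perm_seed = permSeed, cdt_p = cdtP, extent = extent,
                      q = q, min_coverage = minCoverage),
    per_subject = lapply(subjects, function(s)
      c(list(subject_id = subjectId(s$series),
             lambda_global = s$global$lambda_global), s$counts)),
    results = list(n_clusters = nrow(fwe$clusters),
                   min_corrected_p = min(fwe$corrected_p_map),
                   n_significant_cells = sum(scaletest$sig_mask),
                   significant_scales = scaletest$significant_scales))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeVolume(new("LambdaMap", data = fwe$t_map,
                    affine = volAffine(volumes[[1]]), subjectId = "t"),
                file.path(outDir, "group_t.nii.gz"))
    writeVolume(new("LambdaMap", data = fwe$corrected_p_map,
                    affine = volAffine(volumes[[1]]), subjectId = "pFWE"),
                file.path(outDir, "group_pFWE.nii.gz"))
    utils::write.table(fwe$clusters, file.path(outDir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sigcells <- which(scaletest$sig_mask, arr.ind = TRUE)
    utils::write.table(
      data.frame(point = sigcells[, 1],
                 scale = scaletest$scales[sigcells[, 2]],
                 q_value = scaletest$q_grid[sigcells]),
      file.path(outDir, "significant_cells.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(rmeans))
      utils::write.table(rmeans, file.path(outDir, "region_means.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(subjects = subjects, glm = glm, fwe = fwe, scaletest = scaletest,
       region_means = rmeans, manifest = manifest)
}
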