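# ---- design-matrix helpers -------------------------------------------------

# builds [intercept, group indicator, covariates]; group = second factor level
.designMatrix <- function(table, covariateNames) {
  g <- table$group
  if (!is.factor(g)) g <- factor(g)
  if (nlevels(droplevels(g)) != 2L) {
    stop(errorCondition("exactly two groups are required",
                        class = c("chaosgm_bad_groups", "error", "condition")))
  }
  g <- droplevels(g)
  if (min(table(g)) < 2L) {
    stop(errorCondition("each group needs at least 2 subjects",
                        class = c("chaosgm_bad_groups", "error", "condition")))
  }
  for (nm in covariateNames) {
    if (!nm %in% names(table)) {
      stop(errorCondition(sprintf("missing covariate column '%s'", nm),
                          class = c("chaosgm_missing_column", "error", "condition")))
    }
    if (anyNA(table[[nm]])) {
      stop(errorCondition(sprintf("missing values in covariate '%s'", nm),
                          class = c("chaosgm_bad_covariate", "error", "condition")))
    }
  }
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2L]))
  for (nm in covariateNames) X <- cbind(X, as.numeric(table[[nm]]))
  colnames(X) <- c("intercept", "group", covariateNames)
  if (qr(X)$rank < ncol(X)) {
    stop(errorCondition("rank-deficient design (collinear covariates?)",
                        class = c("chaosgm_rank_deficient", "error", "condition")))
  }
  X
}

# vectorized OLS t-statistics for one design column across many responses.
# Y: n x V matrix. Returns list(t, df).
.olsT <- function(Y, X, col = 2L) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  coef <- XtXinv %*% crossprod(X, Y)          # p x V
  res <- Y - X %*% coef
  df <- n - p
  sigma2 <- colSums(res * res) / df
  se <- sqrt(sigma2 * XtXinv[col, col])
  tt <- coef[col, ] / se
  tt[se == 0] <- 0
  list(t = tt, df = df)
}

#' Voxel-wise covariate-adjusted group contrast
#'
#' Ordinary least squares per voxel on the design
#' \code{[intercept, group, covariates]}; the reported statistic is the
#' t-value of the group column (second level minus first, in the factor's
#' level order) with two-sided Student-t p-values at \code{n - p} residual
#' degrees of freedom. The analysis mask is the set of voxels with nonzero
#' variance across subjects. With no covariates this reduces exactly to the
#' pooled-variance two-sample t-test.
#'
#' @param maps List of [LambdaMap-class], one per row of \code{table}.
#' @param table Covariate table (see [readCovariates()]).
#' @param covariateNames Character vector of covariate columns (possibly
#'   empty).
#' @param mask Optional logical 3D array restricting the analysis (e.g. a
#'   [coverageMask()]); intersected with the nonzero-variance mask.
#' @return List of class \code{chaosgm_glm}: \code{t_map}, \code{p_map} (both
#'   3D; 0 and 1 outside the mask), \code{df}, \code{mask} (3D logical),
#'   \code{design}.
#' @export
glmContrast <- function(maps, table, covariateNames = character(),
                        mask = NULL) {
  stopifnot(length(maps) == nrow(table))
  X <- .designMatrix(table, covariateNames)
  shape <- dim(volData(maps[[1]]))
  Y <- vapply(maps, function(m) as.numeric(volData(m)), numeric(prod(shape)))
  Y <- t(Y)                                   # n x V
  v <- apply(Y, 2L, stats::var)
  mask <- if (is.null(mask)) v > 0 else as.logical(mask) & v > 0
  fit <- .olsT(Y[, mask, drop = FALSE], X)
  tmap <- array(0, shape)
  pmap <- array(1, shape)
  tmap[mask] <- fit$t
  pmap[mask] <- 2 * stats::pt(-abs(fit$t), fit$df)
  structure(list(t_map = tmap, p_map = pmap, df = fit$df,
                 mask = array(mask, shape), design = X),
            class = "chaosgm_glm")
}

#' @export
print.chaosgm_glm <- function(x, ...) {
  cat(sprintf("chaosgm GLM contrast: %d mask voxels, df = %d, max |t| = %.3f\n",
              sum(x$mask), x$df, max(abs(x$t_map))))
  invisible(x)
}

# ---- clustering ------------------------------------------------------------

#' Connected components of a 3D mask
#'
#' Labels a logical 3D array with 26-neighbourhood connectivity
#' (face + edge + corner) by breadth-first flood fill.
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape; 0 for background, 1..n for
#'   components.
#' @export
labelClusters <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  coords <- arrayInd(idx, d)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  nextLab <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    queue <- seed
    lab[seed] <- nextLab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      nb <- off + matrix(cc, nrow(off), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[inmask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nextLab
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

# ---- permutation FWE -------------------------------------------------------

#' Permutation maxT family-wise error control
#'
#' Covariate-adjusted permutation inference for the voxel-wise group
#' contrast using the Freedman-Lane scheme: responses are residualised
#' against the nuisance design (intercept + covariates), the residual rows
#' are permuted, and the full-model group t-statistic is recomputed. The
#' voxel-level FWE-corrected p-value is the rank of the observed |t| within
#' the permutation distribution of the maximum |t| over the mask. Clusters
#' are formed on the *uncorrected* t-map at the cluster-defining threshold
#' \code{cdtP} (two-sided) and filtered at the extent threshold with
#' 26-connectivity.
#'
#' @param maps,table,covariateNames As in [glmContrast()].
#' @param nPerm Number of random permutations (>= 100); ignored when
#'   \code{exact = TRUE}.
#' @param seed Integer seed for the permutation stream.
#' @param cdtP Cluster-defining (uncorrected, two-sided) p threshold.
#' @param extent Minimum cluster size in voxels.
#' @param exact If TRUE, enumerate all row permutations (only for
#'   \code{n! <= 50000}, i.e. n <= 8) and report exact permutation p-values.
#' @param mask Optional logical 3D array restricting the analysis (e.g. a
#'   [coverageMask()]); intersected with the nonzero-variance mask.
#' @return List of class \code{chaosgm_fwe}: \code{corrected_p_map},
#'   \code{t_map}, \code{clusters} (data.frame: size_voxels, peak_i/j/k,
#'   peak_t, min_corrected_p), \code{max_t_null}, \code{n_perm}.
#' @export
permutationFWE <- function(maps, table, covariateNames = character(),
                           nPerm = 1000L, seed = 1L, cdtP = 0.001,
                           extent = 10L, exact = FALSE, mask = NULL) {
  if (!exact && nPerm < 100L) {
    stop(errorCondition("nPerm must be >= 100",
                        class = c("chaosgm_too_few_perms", "error", "condition")))
  }
  X <- .designMatrix(table, covariateNames)
  n <- nrow(X)
  shape <- dim(volData(maps[[1]]))
  Y <- t(vapply(maps, function(m) as.numeric(volData(m)), numeric(prod(shape))))
  v <- apply(Y, 2L, stats::var)
  mask <- if (is.null(mask)) v > 0 else as.logical(mask) & v > 0
  if (!any(mask)) {
    stop(errorCondition("degenerate mask: no voxel varies across subjects",
                        class = c("chaosgm_degenerate_mask", "error", "condition")))
  }
  Ym <- Y[, mask, drop = FALSE]
  obs <- .olsT(Ym, X)
  # Freedman-Lane: residualise against nuisance columns
  Z <- X[, -2L, drop = FALSE]
  Rz <- Ym - Z %*% chol2inv(chol(crossprod(Z))) %*% crossprod(Z, Ym)
  perms <- if (exact) {
    if (factorial(n) > 50000) {
      stop(errorCondition("exact enumeration limited to n <= 8",
                          class = c("chaosgm_too_many_perms", "error", "condition")))
    }
    .allPerms(n)
  } else {
    set.seed(as.integer(seed))
    replicate(nPerm, sample.int(n), simplify = FALSE)
  }
  maxT <- vapply(perms, function(pr) {
    max(abs(.olsT(Rz[pr, , drop = FALSE], X)$t))
  }, numeric(1))
  absT <- abs(obs$t)
  if (exact) {
    corr <- vapply(absT, function(t0) mean(maxT >= t0 - 1e-12), numeric(1))
  } else {
    corr <- vapply(absT, function(t0) (1 + sum(maxT >= t0)) / (length(maxT) + 1),
                   numeric(1))
  }
  cpmap <- array(1, shape)
  cpmap[mask] <- corr
  tmap <- array(0, shape)
  tmap[mask] <- obs$t
  # clusters at the cluster-defining threshold on the uncorrected map
  tcdt <- stats::qt(1 - cdtP / 2, obs$df)
  lab <- labelClusters(abs(tmap) >= tcdt & mask)
  clusters <- data.frame(size_voxels = integer(), peak_i = integer(),
                         peak_j = integer(), peak_k = integer(),
                         peak_t = numeric(), min_corrected_p = numeric())
  if (max(lab) > 0) {
    for (cl in seq_len(max(lab))) {
      vox <- which(lab == cl)
      if (length(vox) < extent) next
      pk <- vox[which.max(abs(tmap[vox]))]
      pc <- arrayInd(pk, shape)
      clusters <- rbind(clusters, data.frame(
        size_voxels = length(vox), peak_i = pc[1], peak_j = pc[2],
        peak_k = pc[3], peak_t = tmap[pk],
        min_corrected_p = min(cpmap[vox])))
    }
    if (nrow(clusters)) {
      clusters <- clusters[order(-clusters$size_voxels), , drop = FALSE]
      rownames(clusters) <- NULL
    }
  }
  structure(list(corrected_p_map = cpmap, t_map = tmap, clusters = clusters,
                 max_t_null = maxT, n_perm = length(perms), df = obs$df),
            class = "chaosgm_fwe")
}

#' @export
print.chaosgm_fwe <- function(x, ...) {
  cat(sprintf("chaosgm permutation FWE: %d permutations, min corrected p = %.4g, %d cluster(s)\n",
              x$n_perm, min(x$corrected_p_map), nrow(x$clusters)))
  invisible(x)
}

# all permutations of 1..n (recursive; n <= 8)
.allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPerms(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Coverage-based analysis mask
#'
#' Implicit masking for voxel-wise lambda comparisons, analogous to the
#' absolute-threshold masking used in voxel-based morphometry: each subject's
#' binary selected-voxel support is smoothed with the same Gaussian kernel as
#' the lambda maps, giving the fraction of kernel mass drawn from selected
#' voxels ("coverage"); the mask keeps voxels whose *minimum* coverage across
#' subjects exceeds \code{minCoverage}. This removes edge voxels where some
#' subjects contribute (near-)zero support, whose zero-inflated values would
#' otherwise make the voxel-wise t-test badly calibrated.
#'
#' @param maps List of *unsmoothed* [LambdaMap-class] (support = nonzero set).
#' @param fwhm Smoothing FWHM in mm (match the lambda-map smoothing).
#' @param minCoverage Minimum coverage fraction required in every subject.
#' @return Logical 3D array.
#' @export
coverageMask <- function(maps, fwhm = 8, minCoverage = 0.001) {
  shape <- dim(volData(maps[[1]]))
  mincov <- array(Inf, shape)
  for (m in maps) {
    sel <- array(0, shape)
    sel[volData(m) != 0] <- 1
    sm <- smoothMap(new("LambdaMap", data = sel, affine = volAffine(m),
                        subjectId = "coverage"), fwhm)
    mincov <- pmin(mincov, volData(sm))
  }
  mincov > minCoverage
}

# ---- FDR -------------------------------------------------------------------

#' Benjamini-Hochberg FDR
#'
#' Step-up FDR over a flat vector of p-values. The adjusted value for the
#' i-th order statistic is \eqn{\min_{j \ge i} p_{(j)} n / j}, capped at 1;
#' a hypothesis is rejected iff its adjusted value is \code{<= q}, which is
#' exactly the classical step-up rule (for continuous p-values the boundary
#' case has probability zero).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List: \code{reject} (logical), \code{adjusted} (numeric).
#' @export
bhFdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop(errorCondition("p-values must lie in [0, 1]",
                        class = c("chaosgm_bad_pvalues", "error", "condition")))
  }
  adjusted <- stats::p.adjust(p, method = "BH")
  list(reject = adjusted <= q, adjusted = adjusted)
}

# ---- scalogram group test --------------------------------------------------

# pooled-variance two-sample t per column; A, B: nA x V / nB x V matrices
.twoSampleT <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  ssA <- colSums(A * A) - nA * mA^2
  ssB <- colSums(B * B) - nB * mB^2
  df <- nA + nB - 2L
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tt <- (mA - mB) / se
  tt[se == 0] <- 0
  list(t = tt, df = df)
}

#' Cell-wise scalogram group comparison with FDR control
#'
#' Two-sample t-test across subjects at every (point, scale) cell of the
#' scalogram grid, with Benjamini-Hochberg correction over the full grid
#' (or per scale column when \code{perScale = TRUE}; the field reports both
#' conventions). A scale is "significant" when at least one of its cells
#' survives.
#'
#' @param scalsA,scalsB Lists of [Scalogram-class] of identical shape.
#' @param q FDR level.
#' @param perScale If TRUE, apply BH separately within each scale column.
#' @return List of class \code{chaosgm_scaletest}: \code{t_grid},
#'   \code{p_grid}, \code{q_grid}, \code{sig_mask}, \code{significant_scales},
#'   \code{scales}.
#' @export
scalogramGroupTest <- function(scalsA, scalsB, q = 0.05, perScale = FALSE) {
  if (length(scalsA) < 2L || length(scalsB) < 2L) {
    stop(errorCondition("each group needs at least 2 subjects",
                        class = c("chaosgm_bad_groups", "error", "condition")))
  }
  shp <- dim(scalCoeffs(scalsA[[1]]))
  all_ok <- all(vapply(c(scalsA, scalsB),
                       function(s) identical(dim(scalCoeffs(s)), shp), logical(1)))
  if (!all_ok) {
    stop(errorCondition("scalogram shapes differ",
                        class = c("chaosgm_shape_mismatch", "error", "condition")))
  }
  A <- t(matrix(vapply(scalsA, function(s) as.numeric(scalCoeffs(s)),
                       numeric(prod(shp))), nrow = prod(shp)))
  B <- t(matrix(vapply(scalsB, function(s) as.numeric(scalCoeffs(s)),
                       numeric(prod(shp))), nrow = prod(shp)))
  ts <- .twoSampleT(A, B)
  pg <- matrix(2 * stats::pt(-abs(ts$t), ts$df), shp[1], shp[2])
  if (perScale) {
    qg <- apply(pg, 2L, function(col) bhFdr(col, q)$adjusted)
  } else {
    qg <- matrix(bhFdr(as.numeric(pg), q)$adjusted, shp[1], shp[2])
  }
  sig <- qg <= q
  scales <- scalScales(scalsA[[1]])
  structure(list(t_grid = matrix(ts$t, shp[1], shp[2]), p_grid = pg,
                 q_grid = qg, sig_mask = sig,
                 significant_scales = scales[colSums(sig) > 0],
                 scales = scales, df = ts$df),
            class = "chaosgm_scaletest")
}

#' @export
print.chaosgm_scaletest <- function(x, ...) {
  cat(sprintf("chaosgm scalogram test: %d x %d grid, %d significant cell(s), scales: %s\n",
              nrow(x$p_grid), ncol(x$p_grid), sum(x$sig_mask),
              if (length(x$significant_scales))
                paste(x$significant_scales, collapse = ", ") else "none"))
  invisible(x)
}

# ---- atlas region means ----------------------------------------------------

#' Region means of a lambda map over an atlas
#'
#' Mean of the map over its *nonzero* (selected) voxels within each atlas
#' label; labels containing no selected voxel are reported with
#' \code{n_voxels = 0} and \code{mean = NA}.
#'
#' @param map A [LambdaMap-class].
#' @param atlas Integer-labelled 3D array of the same shape (0 = background).
#' @param labels Labels to report (default: all nonzero labels in the atlas).
#' @return data.frame with columns \code{label}, \code{mean},
#'   \code{n_voxels}.
#' @export
regionMeans <- function(map, atlas, labels = NULL) {
  arr <- volData(map)
  if (!identical(dim(arr), dim(atlas))) {
    stop(errorCondition("atlas shape does not match map",
                        class = c("chaosgm_shape_mismatch", "error", "condition")))
  }
  if (is.null(labels)) labels <- sort(unique(atlas[atlas != 0]))
  sel <- arr != 0
  out <- lapply(labels, function(lb) {
    vox <- sel & atlas == lb
    n <- sum(vox)
    data.frame(label = lb, mean = if (n) mean(arr[vox]) else NA_real_,
               n_voxels = n)
  })
  do.call(rbind, out)
}
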