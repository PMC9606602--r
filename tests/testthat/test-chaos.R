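test_that("delay embedding obeys the row-count and index contract", {
  cfg <- embeddingConfig(m = 2, tau = 1, theiler = 0)
  tr <- embedSeries(1:5, cfg)
  expect_equal(dim(tr), c(4, 2))
  expect_equal(tr[1, ], c(1, 2))

  cfg1 <- embeddingConfig(m = 1, tau = 1, theiler = 0)
  x <- rnorm(10)
  expect_equal(embedSeries(x, cfg1), matrix(x, ncol = 1))

  # N=10, m=3, tau=2 -> M=6, element-wise index arithmetic
  cfg3 <- embeddingConfig(m = 3, tau = 2, theiler = 0)
  tr3 <- embedSeries(x, cfg3)
  expect_equal(nrow(tr3), 6)
  for (k in 1:6) for (a in 1:3) {
    expect_identical(tr3[k, a], x[k + (a - 1) * 2])
  }
  expect_error(embedSeries(1:4, embeddingConfig(m = 5, tau = 1, theiler = 0)),
               class = "chaosgm_series_too_short")
})

test_that("embedding row count M = N - (m-1)*tau over random draws", {
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(1:6, 1); tau <- sample(1:4, 1)
    n <- (m - 1) * tau + sample(2:30, 1)
    x <- rnorm(n)
    tr <- embedSeries(x, embeddingConfig(m = m, tau = tau, theiler = 0))
    expect_equal(nrow(tr), n - (m - 1) * tau)
    k <- sample(nrow(tr), 1); a <- sample(m, 1)
    expect_identical(tr[k, a], x[k + (a - 1) * tau])
  }
})

test_that("nearest neighbours: tie-break, Theiler exhaustion, brute force", {
  # three collinear equally spaced states: middle point ties, smaller index wins
  tr <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(nearestNeighbors(tr, 0), c(2L, 1L, 2L))

  expect_true(all(is.na(nearestNeighbors(matrix(rnorm(8), 4), theiler = 3))))

  set.seed(7)
  for (rep in 1:5) {
    tr <- matrix(rnorm(100), 50, 2)
    th <- sample(0:3, 1)
    nn <- nearestNeighbors(tr, th)
    for (k in 1:50) {
      best <- NA_integer_; bd <- Inf
      for (j in 1:50) {
        if (abs(k - j) <= th) next
        d <- sqrt(sum((tr[k, ] - tr[j, ])^2))
        if (d < bd) { bd <- d; best <- j }
      }
      expect_identical(nn[k], best)
    }
  }
})

test_that("divergence curve: geometric closed form, zero-distance guard, brute force", {
  # x_i = c * r^i separates every neighbour pair exactly exponentially:
  # each reference's log-divergence advances by exactly ln r per step
  # (the k-dependent initial separation d_k(0) cancels per reference)
  r <- 1.3; cc <- 1e-4
  x <- cc * r^(0:40)
  cfg <- embeddingConfig(m = 3, tau = 1, theiler = 1, maxSteps = 10,
                         fitRange = c(1, 10))
  tr <- embedSeries(x, cfg)
  nn <- nearestNeighbors(tr, cfg@theiler)
  ld <- logDivergence(tr, nn, cfg@maxSteps)
  steps_ok <- !is.na(ld)
  perRef <- t(apply(ld, 1, diff))
  expect_equal(perRef[!is.na(perRef)],
               rep(log(r), sum(!is.na(perRef))), tolerance = 1e-9)
  # and the per-reference slope localization recovers ln r wherever defined
  lam <- lambdaLocal(ld, cfg)
  expect_equal(lam[!is.na(lam)], rep(log(r), sum(!is.na(lam))),
               tolerance = 1e-9)

  # duplicated identical rows: zero-distance pairs excluded from counts
  xdup <- c(1, 2, 1, 2, 5, 9, 1, 2)
  cfg2 <- embeddingConfig(m = 2, tau = 1, theiler = 0, maxSteps = 2,
                          fitRange = c(1, 2))
  tr2 <- embedSeries(xdup, cfg2)
  nn2 <- nearestNeighbors(tr2, 0)
  ld2 <- logDivergence(tr2, nn2, 2)
  # rows 1,3,7 embed to (1,2); their NN distance is exactly 0 -> NA at step 0
  expect_true(all(is.na(ld2[c(1, 3, 7), 1])))
  curve2 <- divergenceCurve(tr2, nn2, cfg2)
  expect_lt(curve2$count[1], nrow(tr2))

  # random trajectory equals brute-force recomputation
  set.seed(3)
  x3 <- rnorm(30)
  cfg3 <- embeddingConfig(m = 2, tau = 2, theiler = 2, maxSteps = 5,
                          fitRange = c(1, 5))
  tr3 <- embedSeries(x3, cfg3)
  nn3 <- nearestNeighbors(tr3, cfg3@theiler)
  ld3 <- logDivergence(tr3, nn3, 5)
  M <- nrow(tr3)
  for (k in 1:M) for (s in 0:5) {
    j <- nn3[k]
    exp_val <- if (is.na(j) || k + s > M || j + s > M) NA_real_ else {
      d <- sqrt(sum((tr3[k + s, ] - tr3[j + s, ])^2))
      if (d > 0) log(d) else NA_real_
    }
    expect_equal(ld3[k, s + 1], exp_val, tolerance = 1e-12)
  }
})

test_that("global lambda fit recovers an exact line and flags degenerate fits", {
  cfg <- embeddingConfig(m = 2, tau = 1, theiler = 0, maxSteps = 10,
                         fitRange = c(1, 8))
  curve <- data.frame(step = 0:10, mean_log_div = -3 + 0.25 * (0:10),
                      count = rep(5L, 11))
  est <- lambdaGlobal(curve, cfg)
  expect_equal(est$lambda_global, 0.25, tolerance = 1e-12)
  expect_equal(est$intercept, -3, tolerance = 1e-12)
  expect_equal(est$fit_r2, 1)

  curve$count <- c(5L, 5L, rep(0L, 9))
  expect_error(lambdaGlobal(curve, cfg), class = "chaosgm_degenerate_fit")

  # constant series dies at the divergence stage (all distances zero)
  cfgc <- embeddingConfig(m = 2, tau = 1, theiler = 0, maxSteps = 3,
                          fitRange = c(1, 3))
  trc <- embedSeries(rep(2, 10), cfgc)
  nnc <- nearestNeighbors(trc, 0)
  expect_error(divergenceCurve(trc, nnc, cfgc),
               class = "chaosgm_degenerate_divergence")
})

test_that("local lambda: constant slope, tStep scaling, brute-force slope oracle", {
  cfg <- embeddingConfig(m = 2, tau = 1, theiler = 0, maxSteps = 6,
                         fitRange = c(1, 5))
  # perfectly linear per-reference log-divergence with slope 0.4
  ld <- outer(rnorm(8), rep(1, 7)) + outer(rep(1, 8), 0.4 * (0:6))
  lam <- lambdaLocal(ld, cfg)
  expect_equal(lam, rep(0.4, 8), tolerance = 1e-12)

  cfg2 <- embeddingConfig(m = 2, tau = 1, theiler = 0, tStep = 2,
                          maxSteps = 6, fitRange = c(1, 5))
  expect_equal(lambdaLocal(ld, cfg2), rep(0.2, 8), tolerance = 1e-12)

  # the one-step rule is the finite difference of the first two steps
  expect_equal(lambdaLocal(ld, cfg, method = "difference"),
               (ld[, 2] - ld[, 1]), tolerance = 1e-12)

  # random log-divergences with NAs: matches per-reference lm() fits
  set.seed(12)
  ldr <- matrix(rnorm(8 * 7), 8, 7)
  ldr[sample(56, 10)] <- NA
  lam <- lambdaLocal(ldr, cfg)
  for (k in 1:8) {
    s <- 1:5; y <- ldr[k, s + 1]
    ok <- !is.na(y)
    exp_val <- if (sum(ok) >= 2) unname(coef(lm(y[ok] ~ s[ok]))[2]) else NA_real_
    expect_equal(lam[k], exp_val, tolerance = 1e-9)
  }
})

test_that("lambda map scatters values to selected voxels and round-trips", {
  vi <- rbind(c(2L, 3L, 4L), c(1L, 1L, 1L), c(8L, 8L, 8L))
  ls <- new("LambdaSeries", values = c(0.5, -0.2, 0.9), voxelIndices = vi,
            subjectId = "s")
  m <- lambdaMap(ls, c(8, 8, 8), diag(4))
  expect_equal(sum(volData(m) != 0), 3)
  expect_equal(volData(m)[vi], c(0.5, -0.2, 0.9))

  # flagged-missing values become 0 with a message
  ls2 <- new("LambdaSeries", values = c(0.5, NA, 0.9), voxelIndices = vi,
             subjectId = "s")
  expect_message(m2 <- lambdaMap(ls2, c(8, 8, 8), diag(4)), "1 flagged")
  expect_equal(volData(m2)[vi], c(0.5, 0, 0.9))

  empty <- new("LambdaSeries", values = numeric(),
               voxelIndices = matrix(integer(), 0, 3), subjectId = "s")
  expect_equal(sum(volData(lambdaMap(empty, c(4, 4, 4), diag(4)))), 0)

  bad <- new("LambdaSeries", values = 1, voxelIndices = rbind(c(9L, 1L, 1L)),
             subjectId = "s")
  expect_error(lambdaMap(bad, c(8, 8, 8), diag(4)),
               class = "chaosgm_index_out_of_bounds")
})

test_that("Gaussian smoothing: delta peak, identity limit, constant interior", {
  aff <- diag(c(1.5, 1.5, 1.5, 1))
  arr <- array(0, c(31, 31, 31)); arr[16, 16, 16] <- 1
  m <- new("LambdaMap", data = arr, affine = aff, subjectId = "d")
  sm <- smoothMap(m, fwhm = 8)
  sigma <- 8 / (1.5 * sqrt(8 * log(2)))
  # discrete normalised kernel peak (product over 3 axes)
  r <- ceiling(4 * sigma); tgrid <- (-r):r
  k1 <- exp(-tgrid^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  expect_equal(volData(sm)[16, 16, 16], max(k1)^3, tolerance = 1e-12)
  expect_equal(sum(volData(sm)), 1, tolerance = 1e-6)   # mass preserved

  sm0 <- smoothMap(m, fwhm = 0.01)
  expect_lt(max(abs(volData(sm0) - arr)), 1e-6)

  cst <- new("LambdaMap", data = array(3, c(24, 24, 24)), affine = aff,
             subjectId = "c")
  smc <- smoothMap(cst, fwhm = 8)
  expect_equal(volData(smc)[12, 12, 12], 3, tolerance = 1e-9)
  expect_error(smoothMap(m, fwhm = -1), class = "chaosgm_bad_fwhm")
})

test_that("lambda quantities are invariant to series shift and scale", {
  set.seed(21)
  x <- cumsum(rnorm(400))
  cfg <- embeddingConfig(m = 3, tau = 1, theiler = 2, maxSteps = 10,
                         fitRange = c(1, 8))
  run <- function(x) {
    tr <- embedSeries(x, cfg)
    nn <- nearestNeighbors(tr, cfg@theiler)
    ld <- logDivergence(tr, nn, cfg@maxSteps)
    count <- colSums(!is.na(ld))
    mld <- suppressWarnings(colMeans(ld, na.rm = TRUE))
    list(est = lambdaGlobal(data.frame(step = 0:cfg@maxSteps,
                                       mean_log_div = mld, count = count), cfg),
         local = lambdaLocal(ld, cfg))
  }
  base <- run(x)
  shifted <- run(x + 100)
  scaled <- run(x * 3)
  expect_equal(shifted$est$lambda_global, base$est$lambda_global,
               tolerance = 1e-8)
  expect_equal(scaled$est$lambda_global, base$est$lambda_global,
               tolerance = 1e-8)
  expect_equal(shifted$local, base$local, tolerance = 1e-8)
  expect_equal(scaled$local, base$local, tolerance = 1e-8)
})

test_that("mean of local lambdas matches the global slope on linear curves", {
  cfg <- embeddingConfig(m = 2, tau = 1, theiler = 0, maxSteps = 6,
                         fitRange = c(1, 5))
  ld <- outer(rnorm(20), rep(1, 7)) + outer(rep(1, 20), 0.31 * (0:6))
  count <- colSums(!is.na(ld))
  curve <- data.frame(step = 0:6, mean_log_div = colMeans(ld), count = count)
  est <- lambdaGlobal(curve, cfg)
  expect_equal(mean(lambdaLocal(ld, cfg)), est$lambda_global, tolerance = 1e-10)
})
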