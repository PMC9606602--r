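# builds n LambdaMaps from an n x V value matrix on a given shape
mapsFromMatrix <- function(Y, shape, affine = diag(4)) {
  lapply(seq_len(nrow(Y)), function(i) {
    new("LambdaMap", data = array(Y[i, ], shape), affine = affine,
        subjectId = sprintf("s%02d", i))
  })
}

nullTable <- function(nA, nB, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", seq_len(nA + nB)),
             group = factor(rep(c("A", "B"), c(nA, nB))),
             age = runif(nA + nB, 20, 40),
             sex = rbinom(nA + nB, 1, 0.5))
}

test_that("GLM contrast: null identity, closed-form t, collinearity error", {
  shape <- c(4, 4, 4)
  tab <- nullTable(3, 3)
  Y <- matrix(rep(rnorm(prod(shape)), 6), nrow = 6, byrow = TRUE)
  g <- glmContrast(mapsFromMatrix(Y, shape), tab)
  expect_true(all(g$t_map == 0))

  # one varying voxel, no covariates: equals the pooled-variance two-sample t
  set.seed(2)
  Y2 <- matrix(0, 8, prod(shape))
  Y2[, 5] <- c(rnorm(4, 0), rnorm(4, 1))
  tab2 <- nullTable(4, 4)
  g2 <- glmContrast(mapsFromMatrix(Y2, shape), tab2)
  tt <- t.test(Y2[1:4, 5], Y2[5:8, 5], var.equal = TRUE)
  expect_equal(g2$t_map[5], -tt$statistic[[1]], tolerance = 1e-10)
  expect_equal(g2$p_map[5], tt$p.value, tolerance = 1e-10)
  expect_equal(g2$df, 6)

  tab3 <- nullTable(3, 3)
  tab3$bad <- as.numeric(tab3$group == "B")
  expect_error(glmContrast(mapsFromMatrix(Y, shape), tab3, "bad"),
               class = "chaosgm_rank_deficient")
  expect_error(glmContrast(mapsFromMatrix(Y[1:3, , drop = FALSE], shape),
                           nullTable(1, 2)),
               class = "chaosgm_bad_groups")
})

test_that("covariate adjustment matches lm() per voxel", {
  shape <- c(3, 3, 3)
  set.seed(6)
  tab <- nullTable(5, 5)
  Y <- matrix(rnorm(10 * prod(shape)), 10)
  g <- glmContrast(mapsFromMatrix(Y, shape), tab, c("age", "sex"))
  for (v in c(1, 13, 27)) {
    fit <- summary(lm(Y[, v] ~ I(tab$group == "B") + tab$age + tab$sex))
    expect_equal(g$t_map[v], fit$coefficients[2, "t value"], tolerance = 1e-9)
    expect_equal(g$p_map[v], fit$coefficients[2, "Pr(>|t|)"], tolerance = 1e-9)
  }
})

test_that("26-connectivity clustering labels components correctly", {
  m <- array(FALSE, c(5, 5, 5))
  m[1:2, 1:2, 1] <- TRUE              # component 1
  m[4, 4, 2] <- TRUE                  # touches (5,5,3) only diagonally
  m[5, 5, 3] <- TRUE                  # corner-adjacent -> same component
  m[1, 5, 5] <- TRUE                  # isolated
  lab <- labelClusters(m)
  expect_equal(max(lab), 3)
  expect_equal(lab[4, 4, 2], lab[5, 5, 3])
  expect_true(lab[1, 5, 5] != lab[4, 4, 2])
  expect_equal(sum(lab == lab[1, 1, 1]), 4)
})

test_that("permutation FWE: null behaviour and exact enumeration oracle", {
  shape <- c(3, 3, 3)
  set.seed(10)
  tab <- nullTable(4, 4)
  Y <- matrix(rnorm(8 * prod(shape)), 8)
  fwe <- permutationFWE(mapsFromMatrix(Y, shape), tab, nPerm = 200, seed = 3)
  # under the null the smallest maxT-corrected p is itself ~ uniform; with
  # this seed it sits well away from the significance region
  expect_gte(min(fwe$corrected_p_map), 0.2)
  expect_equal(nrow(fwe$clusters), 0)

  # single-voxel mask: exact permutation p equals label-combination oracle
  Y1 <- matrix(0, 6, prod(shape))
  set.seed(11)
  Y1[, 14] <- rnorm(6) + rep(c(0, 1.2), each = 3)
  tab1 <- nullTable(3, 3)
  ex <- permutationFWE(mapsFromMatrix(Y1, shape), tab1, exact = TRUE,
                       cdtP = 0.001)
  tobs <- abs(t.test(Y1[1:3, 14], Y1[4:6, 14], var.equal = TRUE)$statistic)
  combs <- combn(6, 3)
  tall <- apply(combs, 2, function(ix)
    abs(t.test(Y1[ix, 14], Y1[-ix, 14], var.equal = TRUE)$statistic))
  expect_equal(ex$corrected_p_map[14], mean(tall >= tobs - 1e-12),
               tolerance = 1e-12)

  # relabelling the groups leaves two-sided permutation p unchanged
  tab1b <- tab1
  tab1b$group <- factor(rep(c("B", "A"), each = 3), levels = c("A", "B"))
  exb <- permutationFWE(mapsFromMatrix(Y1, shape), tab1b, exact = TRUE,
                        cdtP = 0.001)
  expect_equal(exb$corrected_p_map, ex$corrected_p_map, tolerance = 1e-12)
})

test_that("a planted strong blob survives the extent threshold", {
  shape <- c(8, 8, 8)
  set.seed(20)
  n <- 12
  Y <- matrix(rnorm(n * prod(shape), sd = 0.2), n)
  blob <- array(FALSE, shape); blob[3:4, 3:4, 3:5] <- TRUE  # 12 voxels, connected
  idx <- which(blob)[1:10]
  Y[7:12, idx] <- Y[7:12, idx] + 5
  tab <- nullTable(6, 6)
  fwe <- permutationFWE(mapsFromMatrix(Y, shape), tab, nPerm = 200, seed = 5,
                        cdtP = 0.001, extent = 10)
  expect_gte(nrow(fwe$clusters), 1)
  expect_gte(fwe$clusters$size_voxels[1], 10)
  expect_lte(fwe$clusters$min_corrected_p[1], 0.05)
})

test_that("BH step-up: edge cases, brute-force oracle, monotonicity", {
  expect_true(all(bhFdr(rep(0, 5))$reject))
  r1 <- bhFdr(rep(1, 5))
  expect_false(any(r1$reject))
  expect_true(all(r1$adjusted == 1))
  expect_error(bhFdr(c(0.5, 1.2)), class = "chaosgm_bad_pvalues")

  set.seed(30)
  for (rep in 1:60) {
    n <- sample(1:12, 1)
    p <- round(runif(n), 3)
    q <- sample(c(0.05, 0.1, 0.25), 1)
    got <- bhFdr(p, q)
    # literal step-up: largest k with p_(k) <= q k / n, reject the k smallest
    o <- order(p)
    ps <- p[o]
    k <- suppressWarnings(max(which(ps <= q * seq_len(n) / n)))
    rej <- logical(n)
    if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
    expect_identical(got$reject, rej)
    expect_equal(got$adjusted, p.adjust(p, "BH"))
  }

  # appending p = 1 never un-rejects anything
  p <- c(0.001, 0.02, 0.4)
  base <- bhFdr(p, 0.05)$reject
  ext <- bhFdr(c(p, 1), 0.05)$reject[1:3]
  expect_true(all(ext[base]))
})

scalogramsFrom <- function(mat3, scales) {
  lapply(seq_len(dim(mat3)[3]), function(i) {
    co <- mat3[, , i, drop = FALSE]
    dim(co) <- dim(mat3)[1:2]
    new("Scalogram", coeffs = co, scales = scales,
        boundary = matrix(FALSE, dim(co)[1], dim(co)[2]),
        subjectId = sprintf("s%d", i))
  })
}

test_that("scalogram group test: reduction to plain t, null calibration, planted band", {
  # single-cell grid reduces to a two-sample t with identity BH
  set.seed(40)
  a <- array(rnorm(10), c(1, 1, 10))
  b <- array(rnorm(10, 1), c(1, 1, 10))
  st <- scalogramGroupTest(scalogramsFrom(a, 1), scalogramsFrom(b, 1))
  tt <- t.test(a[1, 1, ], b[1, 1, ], var.equal = TRUE)
  expect_equal(st$t_grid[1, 1], tt$statistic[[1]], tolerance = 1e-10)
  expect_equal(st$q_grid[1, 1], st$p_grid[1, 1])

  # identically drawn groups: any-rejection fraction bounded near the level
  set.seed(41)
  anyrej <- vapply(1:50, function(i) {
    A <- array(rnorm(100 * 10 * 6), c(100, 10, 6))
    B <- array(rnorm(100 * 10 * 6), c(100, 10, 6))
    st <- scalogramGroupTest(scalogramsFrom(A, 1:10), scalogramsFrom(B, 1:10))
    length(st$significant_scales) > 0
  }, logical(1))
  expect_lte(mean(anyrej), 2 * 0.05 + 0.05)   # 2q plus Monte-Carlo slack

  # effect planted at one scale band: detected, and the discoveries
  # concentrate in the band +/- 2 scales (FDR control still admits a ~q
  # share of false cells anywhere on the grid, so containment is of the
  # bulk of the cells, not the significant-scale set)
  set.seed(42)
  hits <- 0; localized <- 0
  for (i in 1:50) {
    A <- array(rnorm(200 * 20 * 10), c(200, 20, 10))
    B <- array(rnorm(200 * 20 * 10), c(200, 20, 10))
    B[, 8:10, ] <- B[, 8:10, ] + 2          # d = 2 at scales 8-10
    st <- scalogramGroupTest(scalogramsFrom(A, 1:20), scalogramsFrom(B, 1:20))
    cells <- which(st$sig_mask, arr.ind = TRUE)
    if (nrow(cells)) {
      hits <- hits + 1
      if (mean(cells[, 2] >= 6 & cells[, 2] <= 12) >= 0.9) {
        localized <- localized + 1
      }
    }
  }
  expect_gte(hits / 50, 0.8)
  expect_gte(localized / 50, 0.8)

  expect_error(
    scalogramGroupTest(scalogramsFrom(a, 1), scalogramsFrom(array(rnorm(20), c(2, 1, 10)), 1)),
    class = "chaosgm_shape_mismatch")
})

test_that("region means match a brute-force group-by and flag empty labels", {
  set.seed(50)
  shape <- c(6, 6, 6)
  arr <- array(rnorm(prod(shape)) * rbinom(prod(shape), 1, 0.4), shape)
  map <- new("LambdaMap", data = arr, affine = diag(4), subjectId = "m")
  atlas <- array(sample(0:3, prod(shape), replace = TRUE), shape)
  rm <- regionMeans(map, atlas)
  for (lb in 1:3) {
    vox <- atlas == lb & arr != 0
    if (sum(vox)) {
      expect_equal(rm$mean[rm$label == lb], mean(arr[vox]), tolerance = 1e-12)
    }
    expect_equal(rm$n_voxels[rm$label == lb], sum(vox))
  }
  # single label covering everything
  rmAll <- regionMeans(map, array(7L, shape))
  expect_equal(rmAll$mean, mean(arr[arr != 0]))
  # label disjoint from the selected voxels
  atlas2 <- array(0L, shape); atlas2[1, 1, 1] <- 9L
  arr2 <- arr; arr2[1, 1, 1] <- 0
  rm2 <- regionMeans(new("LambdaMap", data = arr2, affine = diag(4),
                         subjectId = "m"), atlas2)
  expect_equal(rm2$n_voxels, 0L)
  expect_true(is.na(rm2$mean))
  expect_error(regionMeans(map, array(1L, c(3, 3, 3))),
               class = "chaosgm_shape_mismatch")
})
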