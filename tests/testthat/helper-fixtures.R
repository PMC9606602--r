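# small random GM volume with strictly positive background so COM is defined
randomVolume <- function(shape = c(6, 6, 6), seed = 1, affine = diag(4),
                         subjectId = "rv") {
  set.seed(seed)
  GMVolume(array(runif(prod(shape)), shape), affine, subjectId)
}

# brute-force center of mass by explicit triple loop (1-based indices)
comOracle <- function(arr) {
  d <- dim(arr)
  acc <- c(0, 0, 0); tot <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- arr[i, j, k]
    acc <- acc + w * c(i, j, k)
    tot <- tot + w
  }
  acc / tot
}

# brute-force weighted distance map: per-voxel world distance x intensity
wdOracle <- function(arr, affine, comWorld) {
  d <- dim(arr)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- (affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    out[i, j, k] <- sqrt(sum((w - comWorld)^2)) * arr[i, j, k]
  }
  out
}

# logistic map orbit from a seeded start
logisticSeries <- function(n, seed = 11) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- runif(1, 0.1, 0.9)
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# small deterministic phantom for pipeline tests
tinyPhantom <- function(seed = 5, shape = c(32, 32, 32), ...) {
  makePhantom(phantomConfig(shape = shape, seed = seed, ...),
              subjectId = paste0("p", seed))
}
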