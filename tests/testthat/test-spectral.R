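block_affinity <- function(sizes, value = 1, seed = NULL) {
  N <- sum(sizes)
  lab <- rep(seq_along(sizes), times = sizes)
  A <- outer(lab, lab, "==") * value
  diag(A) <- 0
  storage.mode(A) <- "double"
  A
}

test_that("affinity is the magnitude of S with a clean diagonal", {
  S <- matrix(c(0, -0.3, -0.3, 0), 2, 2)
  A <- build_affinity(S)
  expect_equal(A[1, 2], 0.3)
  expect_identical(unname(diag(A)), c(0, 0))
  # block structure is preserved
  Sb <- block_affinity(c(3, 4)) * 0.7
  expect_equal(build_affinity(Sb) > 0, Sb > 0)
  # symmetry exact
  set.seed(1)
  M <- matrix(rnorm(25), 5, 5); M <- M + t(M); diag(M) <- 0
  # guard isolated rows
  M[M == 0] <- 0.1; diag(M) <- 0
  expect_identical(build_affinity(M), t(build_affinity(M)))
  # asymmetric input rejected
  expect_error(build_affinity(matrix(1:4, 2, 2)), "symmetric")
  # isolated cell rejected by name
  S0 <- block_affinity(c(3, 4)); S0[7, ] <- 0; S0[, 7] <- 0
  rownames(S0) <- colnames(S0) <- paste0("cell", 1:7)
  expect_error(build_affinity(S0), "cell7")
})

test_that("Laplacian eigenvalues lie in [0, 2] and start at ~0", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(runif(100), 10, 10)
    A <- (A + t(A)) / 2; diag(A) <- 0
    cl <- spectral_cluster(A, k = 3, seed = 1)
    expect_true(all(cl$eigenvalues >= -1e-8))
    expect_true(all(diff(cl$eigenvalues) >= -1e-12))  # ascending
    expect_lt(abs(cl$eigenvalues[1]), 1e-8)
    # full spectrum within [0, 2]
    L <- diag(10) - diag(1 / sqrt(rowSums(A))) %*% A %*%
      diag(1 / sqrt(rowSums(A)))
    ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-8 & ev <= 2 + 1e-8))
  }
})

test_that("block-diagonal affinities are recovered exactly (components oracle)", {
  for (sizes in list(c(5, 8, 7), c(10, 10), c(4, 6, 5, 5))) {
    A <- block_affinity(sizes)
    truth <- rep(seq_along(sizes), times = sizes)
    cl <- spectral_cluster(A, k = length(sizes), seed = 7)
    expect_equal(ari(truth, cl$labels), 1)
    expect_identical(sort(unique(cl$labels)), seq_along(sizes))
  }
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(11)
  A <- matrix(runif(400), 20, 20); A <- (A + t(A)) / 2; diag(A) <- 0
  c1 <- spectral_cluster(A, k = 4, seed = 3)
  c2 <- spectral_cluster(A, k = 4, seed = 3)
  expect_identical(c1$labels, c2$labels)
})

test_that("k = N - 1 on a connected graph produces a singleton cluster", {
  A <- matrix(1, 6, 6); diag(A) <- 0
  cl <- spectral_cluster(A, k = 5, seed = 1)
  expect_true(any(table(cl$labels) == 1))
  expect_identical(length(unique(cl$labels)), 5L)
})

test_that("eigengap counts blocks of a block-diagonal affinity", {
  A <- block_affinity(c(6, 5, 7, 6))
  expect_identical(estimate_k_eigengap(A, k_max = 10), 4L)
  # with unequal block strengths too
  A2 <- block_affinity(c(8, 8, 8))
  A2[1:8, 1:8] <- A2[1:8, 1:8] * 0.3
  diag(A2) <- 0
  expect_identical(estimate_k_eigengap(A2, k_max = 10), 3L)
})

test_that("eigengap on a uniform clique returns the bottom of the range", {
  # complete graph: normalized Laplacian spectrum is 0 then N/(N-1) with
  # multiplicity N-1, so all gaps in [2, k_max] tie at ~0 and the first
  # (k = 2) wins
  N <- 12
  A <- matrix(1, N, N); diag(A) <- 0
  ev <- eigen(diag(N) - (1 / (N - 1)) * A, symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sort(ev), c(0, rep(N / (N - 1), N - 1)), tolerance = 1e-10)
  expect_identical(estimate_k_eigengap(A, k_max = 8), 2L)
})

test_that("more components than k is flagged, not fatal", {
  A <- block_affinity(c(4, 4, 4))
  expect_warning(cl <- spectral_cluster(A, k = 2, seed = 1), "components")
  expect_identical(length(cl$labels), 12L)
})
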