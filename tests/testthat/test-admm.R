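test_that("coefficient update matches a generic dense linear solve", {
  for (trial in 1:100) {
    set.seed(trial)
    n_genes <- sample(5:30, 1)
    N <- sample(4:20, 1)
    X <- matrix(rnorm(n_genes * N), n_genes, N)
    J <- matrix(rnorm(N * N), N, N)
    Y <- matrix(rnorm(N * N), N, N)
    gamma <- runif(1, 0.1, 10)
    got <- update_C(X = X, J = J, Y = Y, gamma = gamma)
    # oracle: solve() on the full system, then zero the diagonal
    XtX <- t(X) %*% X
    expected <- solve(XtX + diag(N) / gamma, XtX + (J - Y) / gamma)
    diag(expected) <- 0
    expect_lt(max(abs(got - expected)), 1e-8)
    expect_identical(unname(diag(got)), rep(0, N))
  }
})

test_that("auxiliary update matches the scalar soft-threshold oracle", {
  soft <- function(v, t) sign(v) * max(abs(v) - t, 0)
  for (trial in 1:20) {
    set.seed(trial)
    N <- 8
    C <- matrix(rnorm(N * N, sd = 0.5), N, N)
    Y <- matrix(rnorm(N * N, sd = 0.5), N, N)
    W <- matrix(runif(N * N), N, N)
    W[W < 0.15] <- 0                      # some hard zeros
    W <- (W + t(W)) / 2; diag(W) <- 0
    lambda <- runif(1, 0.01, 0.2)
    gamma <- runif(1, 0.2, 5)
    J <- update_J(C, Y, W, lambda, gamma)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      expected <- if (i == j || W[i, j] == 0) 0 else
        soft(C[i, j] + Y[i, j], lambda * gamma / W[i, j])
      expect_equal(J[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("soft-threshold arithmetic on known values", {
  # V = 0.5, threshold 0.2 -> 0.3
  C <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  Y <- matrix(0, 2, 2)
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(update_J(C, Y, W, lambda = 0.2, gamma = 1)[1, 2], 0.3)
  # below the threshold -> exact zero
  expect_identical(update_J(C, Y, W, lambda = 0.6, gamma = 1)[1, 2], 0)
  # W = 0 -> exact zero whatever V
  W0 <- matrix(0, 2, 2)
  expect_identical(update_J(C * 100, Y, W0, 0.01, 1)[1, 2], 0)
})

test_that("dual update is plain dual ascent on C - J", {
  N <- 4
  set.seed(9)
  C <- matrix(rnorm(N * N), N, N)
  Y0 <- matrix(rnorm(N * N), N, N)
  # zero primal residual leaves Y unchanged
  expect_identical(update_Y(Y0, C, C, gamma = 3), Y0)
  # direct arithmetic: Y = 0, gamma = 2, C - J = 1 -> 0.5 everywhere
  ones <- matrix(1, N, N)
  expect_equal(update_Y(matrix(0, N, N), ones, matrix(0, N, N), 2),
               ones * 0.5)
  # linearity: two applications with fixed residual advance by (2/gamma) R
  R <- matrix(rnorm(N * N), N, N)
  Y2 <- update_Y(update_Y(Y0, R, 0 * R, 4), R, 0 * R, 4)
  expect_equal(Y2, Y0 + 2 * R / 4, tolerance = 1e-14)
})

test_that("gamma schedule reproduces the residual-balancing branch table", {
  expect_equal(update_gamma(1, 100, 1, mu = 50), 0.5)   # primal dominates
  expect_equal(update_gamma(1, 1, 100, mu = 50), 2)     # dual dominates
  expect_equal(update_gamma(1, 1, 1, mu = 50), 1)       # balanced
  expect_equal(update_gamma(0.8, 51, 1, mu = 50), 0.4)
  expect_equal(update_gamma(0.8, 1, 51, mu = 50), 1.6)
  # boundary: exactly mu-fold difference is "others"
  expect_equal(update_gamma(2, 50, 1, mu = 50), 2)
  expect_equal(update_gamma(2, 1, 50, mu = 50), 2)
})

test_that("solver is deterministic and honours its stopping contract", {
  sim <- canonical_fixture()
  pack <- fit_fixture(sim)
  fit <- pack$fit
  fit2 <- ssc_solve(pack$X, pack$W)
  expect_identical(fit$C, fit2$C)
  expect_identical(fit$S, fit2$S)
  expect_identical(fit$residuals, fit2$residuals)

  expect_true(fit$converged)
  expect_lte(fit$n_iter, fit$max_iter)
  expect_lt(max(abs(fit$C - (fit$S - t(fit$C)))), 1e-12)  # S = C' + C
  expect_identical(fit$S, t(fit$S))
  expect_identical(unname(diag(fit$C)), rep(0, ncol(pack$X)))
  # stopping quantity honoured
  expect_lt(fit$residuals$max_gap[fit$n_iter], fit$tol)
})

test_that("hard zeros in W are conserved: J exactly zero, C below tol", {
  sim <- canonical_fixture()
  pack <- fit_fixture(sim)
  X <- pack$X; W <- pack$W; fit <- pack$fit
  # reconstruct the final J by replaying the last update
  zero <- W == 0; diag(zero) <- TRUE
  gamma_last <- fit$residuals$gamma[fit$n_iter]
  # solver guarantees |C| < tol wherever W = 0 once converged
  expect_true(fit$converged)
  expect_lt(max(abs(fit$C[zero])), fit$tol)
  # direct contract of the J update under any inputs
  J <- update_J(fit$C, matrix(1, ncol(X), ncol(X)), W, 0.03, gamma_last)
  expect_identical(unname(J[zero]), rep(0, sum(zero)))
})

test_that("noiseless orthogonal subspaces give a block-diagonal solution", {
  sim <- canonical_fixture()            # noise_sd = 0
  pack <- fit_fixture(sim)
  same <- outer(sim$labels, sim$labels, "==")
  mass_in <- sum(abs(pack$fit$C)[same]) / sum(abs(pack$fit$C))
  expect_gte(mass_in, 0.99)
  expect_lt(max(abs(pack$fit$S)[!same]), 1e-6)
})

test_that("increasing lambda never increases the nonzero count of C", {
  sim <- canonical_fixture()
  X <- l2_normalize_columns(filter_genes(sim$expression))
  W <- compute_weights(X)
  grid <- c(0.01, 0.05, 0.09, 0.13, 0.19)
  nnz <- vapply(grid, function(l) {
    fit <- ssc_solve(X, W, lambda = l)
    c_sparsity(fit$C) * ncol(X) * (ncol(X) - 1)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("lambda selection follows the sparsity-band rule", {
  sim <- canonical_fixture()
  X <- l2_normalize_columns(filter_genes(sim$expression))
  W <- compute_weights(X)
  # huge lambda shrinks C to ~nothing: flagged out-of-range
  expect_warning(sel <- select_lambda(X, W, grid = c(50)), "no lambda")
  expect_false(sel$in_range)
  expect_error(select_lambda(X, W, grid = numeric(0)), "empty")
})

test_that("lambda selection prefers the sparsity closest to the band midpoint", {
  # drive the selection logic directly through a stubbed sparsity table by
  # using tiny problems whose sparsity we can steer with lambda; the
  # midpoint rule itself is unit-tested via the returned table
  sim <- canonical_fixture()
  X <- l2_normalize_columns(filter_genes(sim$expression))
  W <- compute_weights(X)
  grid <- c(0.05, 0.19)
  sel <- select_lambda(X, W, grid = grid, sparsity_range = c(0.02, 0.9))
  # both qualify (band is wide); winner must be the sparsity nearest 0.46
  tab <- sel$table
  expect_true(sel$in_range)
  expect_equal(sel$lambda,
               tab$lambda[which.min(abs(tab$sparsity - 0.46))])
})
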