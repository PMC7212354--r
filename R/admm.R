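#' @title ADMM solver for adaptive sparse subspace clustering
#'
#' @description
#' Solves the self-expressive program
#' \deqn{\min_C \tfrac12\|X - XC\|_F^2 + \lambda \, |J \oslash W|_1
#'       \quad \mathrm{s.t.}\ \mathrm{diag}(C) = 0,\ C = J}
#' where \eqn{X} is the L2-normalized genes-by-cells matrix, \eqn{W} the
#' adaptive weight matrix of [compute_weights()] and \eqn{\oslash}
#' elementwise division. Each cell is expressed as a sparse non-trivial
#' linear combination of the other cells; coefficients between positively
#' correlated cells are penalized less. The three ADMM blocks are iterated
#' with an augmented-Lagrangian parameter `gamma` that is rebalanced from
#' the primal/dual residuals every `gamma_update_every` iterations.
#'
#' @details
#' Per iteration, with current auxiliary `J`, dual `Y` and parameter
#' `gamma`:
#' \itemize{
#'   \item `C <- solve(X'X + (1/gamma) I, X'X + (1/gamma)(J - Y))`, then
#'     `diag(C) <- 0` ([update_C()]);
#'   \item `J <- soft_threshold(C + Y, lambda * gamma / W)` elementwise,
#'     with `J = 0` forced wherever `W = 0` and on the diagonal
#'     ([update_J()]);
#'   \item `Y <- Y + (1/gamma)(C - J)` ([update_Y()]).
#' }
#' The primal residual is `r = C - J` and the dual residual
#' `s = (1/gamma)(J - J_prev)` (entrywise 2-norms). Every
#' `gamma_update_every` iterations `gamma` is halved when
#' `||r|| > mu ||s||`, doubled when `||s|| > mu ||r||`, else kept
#' ([update_gamma()]); the Cholesky factor of `X'X + (1/gamma) I` is cached
#' and rebuilt only when `gamma` changes. Iteration stops when
#' `max(abs(C - J)) < tol` or after `max_iter` iterations. All state starts
#' at zero, so the solver is fully deterministic.
#'
#' @param X Genes-by-cells matrix with unit-norm columns
#'   (see [l2_normalize_columns()]).
#' @param W N x N adaptive weight matrix from [compute_weights()]. Entries
#'   equal to zero (and the diagonal) are hard-zero positions for `J`.
#' @param lambda Positive L1 penalty factor; default 0.03.
#' @param mu Residual-balance ratio for the gamma schedule; default 50.
#' @param gamma0 Initial augmented-Lagrangian parameter; default 1.
#' @param tol Stopping tolerance on `max(abs(C - J))`; default 1e-4.
#' @param max_iter Iteration cap; default 200.
#' @param gamma_update_every Rebalance `gamma` every this many iterations;
#'   default 10.
#' @return An object of class `ssc_fit`: list with elements
#'   \item{C}{N x N coefficient matrix, zero diagonal;}
#'   \item{S}{symmetrized similarity `t(C) + C`;}
#'   \item{converged}{`TRUE` iff the tolerance was met within the cap;}
#'   \item{n_iter}{iterations run;}
#'   \item{residuals}{data.frame with per-iteration `iter`, `primal`,
#'     `dual`, `gamma`, `max_gap` (the stopping quantity);}
#'   \item{lambda, mu, gamma0, tol, max_iter, gamma_update_every}{the
#'     configuration used.}
#' @examples
#' sim <- simulate_subspace_cells(n_clusters = 2, cells_per_cluster = 10,
#'                                n_genes = 24, subspace_dim = 2,
#'                                noise_sd = 0)
#' X <- l2_normalize_columns(filter_genes(sim$expression))
#' fit <- ssc_solve(X, compute_weights(X))
#' fit$converged
#' @export
ssc_solve <- function(X, W, lambda = 0.03, mu = 50, gamma0 = 1,
                      tol = 1e-4, max_iter = 200, gamma_update_every = 10) {
  N <- ncol(X)
  if (N < 2L) stop("need at least 2 cells, got ", N)
  if (!is.matrix(W) || nrow(W) != N || ncol(W) != N) {
    stop("W must be ", N, " x ", N, " to match X")
  }
  stopifnot(lambda > 0, mu > 0, gamma0 > 0, tol > 0,
            max_iter >= 1, gamma_update_every >= 1)

  XtX <- crossprod(X)
  zero_mask <- W == 0
  diag(zero_mask) <- TRUE
  C <- J <- Y <- matrix(0, N, N)
  gamma <- gamma0
  R <- chol(XtX + diag(N) / gamma)
  res <- matrix(NA_real_, max_iter, 5L,
                dimnames = list(NULL,
                                c("iter", "primal", "dual", "gamma",
                                  "max_gap")))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    J_prev <- J
    C <- update_C(XtX = XtX, J = J, Y = Y, gamma = gamma, chol_factor = R)
    J <- update_J(C, Y, W, lambda, gamma, zero_mask = zero_mask)
    Y <- update_Y(Y, C, J, gamma)
    if (any(!is.finite(C)) || any(!is.finite(J))) {
      stop("non-finite solver state at iteration ", it)
    }
    primal <- sqrt(sum((C - J)^2))
    dual <- sqrt(sum((J - J_prev)^2)) / gamma
    max_gap <- max(abs(C - J))
    res[it, ] <- c(it, primal, dual, gamma, max_gap)
    if (max_gap < tol) {
      converged <- TRUE
      break
    }
    if (it %% gamma_update_every == 0L) {
      gamma_new <- update_gamma(gamma, primal, dual, mu)
      if (gamma_new != gamma) {
        gamma <- gamma_new
        R <- chol(XtX + diag(N) / gamma)
      }
    }
  }
  S <- t(C) + C
  dimnames(C) <- dimnames(S) <- list(colnames(X), colnames(X))
  structure(
    list(C = C, S = S, converged = converged, n_iter = it,
         residuals = as.data.frame(res[seq_len(it), , drop = FALSE]),
         lambda = lambda, mu = mu, gamma0 = gamma0, tol = tol,
         max_iter = max_iter, gamma_update_every = gamma_update_every),
    class = "ssc_fit")
}

#' @export
print.ssc_fit <- function(x, ...) {
  cat("Adaptive sparse subspace fit\n")
  cat("  cells:", ncol(x$C), "  lambda:", x$lambda, "\n")
  cat("  ", if (x$converged) "converged" else "iteration cap reached",
      "after", x$n_iter, "iterations (max|C - J| =",
      format(x$residuals$max_gap[x$n_iter], digits = 3), ")\n")
  cat("  off-diagonal sparsity of C:",
      format(c_sparsity(x$C), digits = 3), "\n")
  invisible(x)
}

#' One coefficient-matrix update of the ADMM
#'
#' Solves `(X'X + (1/gamma) I) C = X'X + (1/gamma)(J - Y)` and zeroes the
#' diagonal. Pass `chol_factor` (upper-triangular Cholesky factor of the
#' left-hand side) to reuse a cached factorization; otherwise it is
#' computed here.
#'
#' @param X Optional genes-by-cells matrix (used only if `XtX` missing).
#' @param J,Y Current auxiliary and dual matrices.
#' @param gamma Current augmented-Lagrangian parameter (> 0).
#' @param XtX Optional precomputed Gram matrix `crossprod(X)`.
#' @param chol_factor Optional `chol(XtX + diag(N)/gamma)`.
#' @return Updated coefficient matrix with zero diagonal.
#' @export
update_C <- function(X = NULL, J, Y, gamma, XtX = NULL, chol_factor = NULL) {
  if (is.null(XtX)) {
    if (is.null(X)) stop("provide X or XtX")
    XtX <- crossprod(X)
  }
  if (!all(is.finite(J)) || !all(is.finite(Y)) || !is.finite(gamma)) {
    stop("non-finite inputs to coefficient update")
  }
  if (gamma <= 0) stop("gamma must be positive")
  if (is.null(chol_factor)) {
    chol_factor <- chol(XtX + diag(nrow(XtX)) / gamma)
  }
  B <- XtX + (J - Y) / gamma
  C <- backsolve(chol_factor, forwardsolve(t(chol_factor), B))
  diag(C) <- 0
  C
}

#' One auxiliary-matrix update of the ADMM (weighted soft-threshold)
#'
#' Elementwise shrinkage of `V = C + Y`:
#' `J = sign(V) * max(|V| - lambda * gamma / W, 0)`, with `J = 0` forced
#' wherever `W = 0` (infinite penalty: non-positively correlated pairs) and
#' on the diagonal.
#'
#' @param C,Y Current coefficient and dual matrices.
#' @param W Adaptive weight matrix.
#' @param lambda,gamma Penalty factor and augmented-Lagrangian parameter.
#' @param zero_mask Optional logical matrix of hard-zero positions
#'   (default: `W == 0` plus the diagonal).
#' @return Updated auxiliary matrix.
#' @export
update_J <- function(C, Y, W, lambda, gamma, zero_mask = NULL) {
  if (is.null(zero_mask)) {
    zero_mask <- W == 0
    diag(zero_mask) <- TRUE
  }
  V <- C + Y
  thr <- matrix(Inf, nrow(W), ncol(W))
  thr[!zero_mask] <- lambda * gamma / W[!zero_mask]
  J <- sign(V) * pmax(abs(V) - thr, 0)
  J[zero_mask] <- 0
  diag(J) <- 0
  J
}

#' One dual-variable update of the ADMM
#'
#' `Y <- Y + (1/gamma) (C - J)`: the dual ascent step on the equality
#' constraint `C = J`.
#'
#' @param Y Current dual matrix.
#' @param C,J Current coefficient and auxiliary matrices.
#' @param gamma Augmented-Lagrangian parameter.
#' @return Updated dual matrix.
#' @export
update_Y <- function(Y, C, J, gamma) {
  Y + (C - J) / gamma
}

#' Residual-balancing update of the augmented-Lagrangian parameter
#'
#' Halves `gamma` when the primal residual dominates the dual residual by a
#' factor `mu`, doubles it when the dual dominates by the same factor, and
#' leaves it unchanged otherwise.
#'
#' @param gamma Current value (> 0).
#' @param primal_norm,dual_norm Entrywise 2-norms of the primal residual
#'   `C - J` and dual residual `(1/gamma)(J - J_prev)`.
#' @param mu Balance ratio; default 50.
#' @return Updated gamma.
#' @export
update_gamma <- function(gamma, primal_norm, dual_norm, mu = 50) {
  stopifnot(gamma > 0, primal_norm >= 0, dual_norm >= 0, mu > 0)
  if (primal_norm > mu * dual_norm) {
    gamma / 2
  } else if (dual_norm > mu * primal_norm) {
    2 * gamma
  } else {
    gamma
  }
}

#' Off-diagonal sparsity of a coefficient matrix
#'
#' Fraction of off-diagonal entries counted as nonzero. An entry counts
#' when its magnitude exceeds `max(rel_eps * max(abs(C)), abs_eps)`. The
#' absolute floor matters because an ADMM iterate equals the truly sparse
#' auxiliary matrix only up to the stopping tolerance: entries below that
#' tolerance are optimization residue, not support, and counting them
#' would wash out the sparsity signal entirely.
#'
#' @param C Square coefficient matrix.
#' @param rel_eps Relative magnitude threshold; default 1e-6.
#' @param abs_eps Absolute floor, default 1e-4 (the solver's default
#'   stopping tolerance on `max|C - J|`).
#' @return Fraction in `[0, 1]`.
#' @export
c_sparsity <- function(C, rel_eps = 1e-6, abs_eps = 1e-4) {
  off <- row(C) != col(C)
  m <- max(abs(C))
  if (m == 0) return(0)
  mean(abs(C[off]) > max(rel_eps * m, abs_eps))
}

#' Select the L1 penalty factor by the sparsity rule
#'
#' Runs [ssc_solve()] for every value of `grid` and selects the `lambda`
#' whose converged coefficient sparsity (see [c_sparsity()]) falls inside
#' `sparsity_range`; among several qualifying values the one with sparsity
#' closest to the range midpoint wins. When no value qualifies, the
#' `lambda` with sparsity closest to the range is returned with
#' `in_range = FALSE`.
#'
#' @param X,W As for [ssc_solve()].
#' @param grid Ascending vector of candidate positive `lambda` values.
#' @param sparsity_range Admissible sparsity band `(low, high)`,
#'   default `c(0.02, 0.05)`.
#' @param ... Further arguments passed to [ssc_solve()].
#' @return List with `lambda` (the selection), `in_range` (logical flag),
#'   and `table` (data.frame of `lambda`, `sparsity`, `converged` for the
#'   whole grid).
#' @export
select_lambda <- function(X, W, grid, sparsity_range = c(0.02, 0.05), ...) {
  if (length(grid) == 0L) stop("lambda grid is empty")
  stopifnot(all(grid > 0), !is.unsorted(grid),
            length(sparsity_range) == 2L,
            sparsity_range[1L] > 0, sparsity_range[2L] < 1,
            sparsity_range[1L] < sparsity_range[2L])
  sparsity <- converged <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fit <- ssc_solve(X, W, lambda = grid[i], ...)
    sparsity[i] <- c_sparsity(fit$C)
    converged[i] <- fit$converged
  }
  tab <- data.frame(lambda = grid, sparsity = sparsity,
                    converged = as.logical(converged))
  inside <- sparsity >= sparsity_range[1L] & sparsity <= sparsity_range[2L]
  if (any(inside)) {
    mid <- mean(sparsity_range)
    pick <- which(inside)[which.min(abs(sparsity[inside] - mid))]
    in_range <- TRUE
  } else {
    dist <- pmax(sparsity_range[1L] - sparsity,
                 sparsity - sparsity_range[2L], 0)
    pick <- which.min(dist)
    in_range <- FALSE
    warning("no lambda in the grid attains sparsity in [",
            sparsity_range[1L], ", ", sparsity_range[2L],
            "]; returning the closest (lambda = ", grid[pick],
            ", sparsity = ", signif(sparsity[pick], 3), ")")
  }
  list(lambda = grid[pick], in_range = in_range, table = tab)
}
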