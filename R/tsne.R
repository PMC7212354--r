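#' Joint t-SNE probabilities from a learned similarity matrix
#'
#' Replaces the Gaussian-kernel affinities of standard t-SNE with the
#' learned cell-cell similarity: `P_raw = abs(S)` with zero diagonal, each
#' row normalized to sum 1 (conditional form), then symmetrized to the
#' joint distribution `P = (P_raw + t(P_raw)) / (2 N)`. No perplexity
#' calibration is performed; the similarity already encodes the
#' neighborhood structure.
#'
#' @param S Symmetric square similarity matrix (e.g. `ssc_solve(...)$S`).
#' @return N x N joint probability matrix: non-negative, zero diagonal,
#'   entries summing to 1.
#' @export
similarity_to_p <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be a square matrix")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  P <- abs(S)
  diag(P) <- 0
  rs <- rowSums(P)
  zero <- which(rs == 0)
  if (length(zero)) {
    ids <- if (is.null(rownames(S))) zero else rownames(S)[zero]
    stop("cell(s) with zero similarity to all others: ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  P <- P / rs
  P <- (P + t(P)) / (2 * nrow(S))
  P
}

#' t-SNE embedding from precomputed joint probabilities
#'
#' Minimizes the Kullback–Leibler divergence `KL(P || Q)` between the given
#' joint probabilities and a Student-t kernel `Q` over 2-D coordinates, by
#' gradient descent with momentum, adaptive per-coordinate gains, and early
#' exaggeration. Deterministic under `seed`.
#'
#' @param P Joint probability matrix from [similarity_to_p()].
#' @param seed Integer seed for the random normal initialization
#'   (scaled by 1e-4).
#' @param n_iter Number of gradient iterations; default 1000. With
#'   `n_iter = 0` the seeded initialization is returned unchanged.
#' @param learning_rate Gradient step size. The default `NULL` uses the
#'   sample-size-scaled rule `max(N / early_exaggeration, 10)`: fixed large
#'   step sizes tuned for thousands of points overshoot on small datasets
#'   and leave the late-phase objective oscillating instead of descending.
#' @param early_exaggeration Factor multiplying P during the first
#'   `exaggeration_iter` iterations; default 12.
#' @param exaggeration_iter Length of the early-exaggeration phase (also
#'   when momentum switches from 0.5 to 0.8); default 250.
#' @return An object of class `ssc_tsne`: list with `coords` (N x 2 matrix,
#'   rownames = cell ids), `kl_trace` (KL divergence against the
#'   unexaggerated P at every iteration), `seed`, and `params`.
#' @export
tsne_embed <- function(P, seed = 1L, n_iter = 1000L, learning_rate = NULL,
                       early_exaggeration = 12, exaggeration_iter = 250L) {
  N <- nrow(P)
  if (ncol(P) != N) stop("P must be square")
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  if (is.null(learning_rate)) {
    learning_rate <- max(N / early_exaggeration, 10)
  }
  set.seed(seed)
  Yc <- matrix(rnorm(N * 2L, sd = 1e-4), N, 2L)
  if (n_iter == 0L) {
    return(structure(
      list(coords = structure(Yc, dimnames = list(rownames(P), c("x", "y"))),
           kl_trace = numeric(0), seed = seed,
           params = list(n_iter = 0L, learning_rate = learning_rate,
                         early_exaggeration = early_exaggeration,
                         exaggeration_iter = exaggeration_iter)),
      class = "ssc_tsne"))
  }
  P <- pmax(P, .Machine$double.xmin)
  gains <- matrix(1, N, 2L)
  inc <- matrix(0, N, 2L)
  kl_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    exag <- if (it <= exaggeration_iter) early_exaggeration else 1
    momentum <- if (it <= exaggeration_iter) 0.5 else 0.8
    # Student-t kernel on current coordinates
    sq <- rowSums(Yc^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Yc))
    diag(num) <- 0
    Q <- num / sum(num)
    kl_trace[it] <- sum(P * log(P / pmax(Q, .Machine$double.xmin)))
    # gradient: 4 * sum_j (exag*P - Q)_ij num_ij (y_i - y_j)
    L <- (exag * P - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Yc
    if (any(!is.finite(G))) {
      stop("non-finite t-SNE gradient at iteration ", it)
    }
    gains <- ifelse(sign(G) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gains * G
    Yc <- Yc + inc
    Yc <- sweep(Yc, 2L, colMeans(Yc))
  }
  structure(
    list(coords = structure(Yc, dimnames = list(rownames(P), c("x", "y"))),
         kl_trace = kl_trace, seed = seed,
         params = list(n_iter = n_iter, learning_rate = learning_rate,
                       early_exaggeration = early_exaggeration,
                       exaggeration_iter = exaggeration_iter)),
    class = "ssc_tsne")
}

#' @export
print.ssc_tsne <- function(x, ...) {
  cat("t-SNE embedding of", nrow(x$coords), "cells (",
      x$params$n_iter, "iterations, final KL =",
      if (length(x$kl_trace)) format(x$kl_trace[length(x$kl_trace)],
                                     digits = 4) else "NA", ")\n")
  invisible(x)
}
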