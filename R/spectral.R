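#' Affinity matrix from a learned similarity
#'
#' Converts the (possibly signed) symmetrized coefficient matrix
#' `S = t(C) + C` into a non-negative graph affinity: `A = abs(S)` with a
#' zero diagonal. Taking magnitudes is the established sparse-subspace
#' convention and preserves the zero pattern of S.
#'
#' @param S Symmetric square similarity matrix.
#' @return Symmetric non-negative affinity matrix with zero diagonal.
#' @export
build_affinity <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be a square matrix")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  A <- abs(S)
  A <- (A + t(A)) / 2    # exact symmetry
  diag(A) <- 0
  isolated <- which(rowSums(A) == 0)
  if (length(isolated)) {
    ids <- if (is.null(rownames(A))) isolated else rownames(A)[isolated]
    stop("isolated cell(s) with no similarity to any other cell: ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  A
}

# Symmetric normalized graph Laplacian I - D^{-1/2} A D^{-1/2}.
normalized_laplacian <- function(A) {
  d_inv_sqrt <- 1 / sqrt(rowSums(A))
  L <- diag(nrow(A)) - d_inv_sqrt * sweep(A, 2L, d_inv_sqrt, "*")
  (L + t(L)) / 2
}

# Eigenvalues ascending, eigenvectors aligned; dense symmetric solver.
laplacian_eigen <- function(A, n = nrow(A)) {
  e <- eigen(normalized_laplacian(A), symmetric = TRUE)
  idx <- rev(seq_len(nrow(A)))[seq_len(n)]   # eigen() sorts decreasing
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' Normalized spectral clustering of a cell affinity graph
#'
#' Forms the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}`, takes the eigenvectors of its `k`
#' smallest eigenvalues, row-normalizes the resulting N x k spectral
#' embedding to unit norm, and partitions it with k-means (best of
#' `n_restarts` random initializations under `seed`).
#'
#' @param A Affinity matrix from [build_affinity()].
#' @param k Number of clusters, `2 <= k <= N - 1`.
#' @param seed Integer seed making the k-means restarts reproducible.
#' @param n_restarts Number of k-means initializations; default 20.
#' @return An object of class `ssc_clustering`: list with integer `labels`
#'   in `1..k` (named by cell id when A has dimnames), `k`, `eigenvalues`
#'   (the k + 1 smallest, ascending), `n_components` (connected components
#'   of the affinity graph), and `seed`.
#' @examples
#' A <- matrix(0, 6, 6)
#' A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
#' spectral_cluster(A, k = 2)$labels
#' @export
spectral_cluster <- function(A, k, seed = 1L, n_restarts = 20L) {
  N <- nrow(A)
  if (k < 2L || k > N - 1L) stop("k must be in [2, N - 1], got ", k)
  eig <- laplacian_eigen(A, n = min(k + 1L, N))
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, .Machine$double.eps)
  n_comp <- sum(eig$values < 1e-8)
  if (n_comp > k) {
    warning("affinity graph has ", n_comp,
            " connected components but k = ", k, " clusters were requested")
  }
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = n_restarts, iter.max = 100L)
  labels <- km$cluster
  names(labels) <- rownames(A)
  structure(
    list(labels = labels, k = k, eigenvalues = eig$values,
         n_components = n_comp, seed = seed),
    class = "ssc_clustering")
}

#' @export
print.ssc_clustering <- function(x, ...) {
  cat("Spectral clustering:", length(x$labels), "cells into", x$k,
      "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Computes the `k_max + 1` smallest eigenvalues of the normalized
#' Laplacian of `A` and returns the `k` in `[2, k_max]` maximizing the gap
#' `eigenvalue[k + 1] - eigenvalue[k]` (first maximizer on ties). For an
#' affinity with `k` well-separated blocks the zero eigenvalue has
#' multiplicity `k`, so the gap after index `k` dominates.
#'
#' @param A Affinity matrix from [build_affinity()].
#' @param k_max Upper end of the search range; default 20 (capped at
#'   `N - 1`).
#' @return Integer estimate of the number of clusters.
#' @export
estimate_k_eigengap <- function(A, k_max = 20L) {
  N <- nrow(A)
  k_max <- min(as.integer(k_max), N - 1L)
  if (k_max < 2L) stop("k_max must be at least 2")
  ev <- laplacian_eigen(A, n = k_max + 1L)$values
  ks <- 2:k_max
  gaps <- ev[ks + 1L] - ev[ks]
  # smallest k among floating-point ties for the largest gap
  ks[which(gaps >= max(gaps) - 1e-9)][1L]
}
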