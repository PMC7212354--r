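#' Simulate subspace-structured single-cell expression data
#'
#' Generates a genes-by-cells matrix in which each cluster of cells lies in
#' its own low-dimensional linear subspace of gene space — the geometric
#' regime the subspace clustering model assumes — plus Gaussian noise and
#' dropout-style zero inflation.
#'
#' In `"orthogonal"` mode each cluster is assigned a disjoint block of
#' genes (its marker genes) and a basis of `subspace_dim` orthonormal
#' non-negative vectors supported on disjoint sub-blocks of that block;
#' cells are non-negative linear combinations (coefficients
#' `Uniform(0.2, 2)`) of their cluster basis. Cluster subspaces are then
#' mutually orthogonal with disjoint gene support, giving an exactly
#' block-diagonal Gram matrix — the regime with an analytic
#' block-diagonality oracle. Requires
#' `n_genes >= n_clusters * subspace_dim`.
#'
#' In `"oblique"` mode bases are random orthonormal frames (QR of Gaussian
#' matrices) with no orthogonality across clusters; cell values are shifted
#' by the global minimum to be non-negative. This is the stress regime:
#' subspaces intersect at random angles.
#'
#' After construction, independent `N(0, noise_sd)` noise is added, entries
#' are zeroed independently with probability `dropout_rate`, and values are
#' clipped at 0.
#'
#' @param n_clusters Number of cell clusters; default 3.
#' @param cells_per_cluster Cells per cluster: scalar or vector of length
#'   `n_clusters`; default 40.
#' @param n_genes Number of genes; default 60.
#' @param subspace_dim Dimension of each cluster subspace; default 4.
#' @param noise_sd Standard deviation of additive Gaussian noise;
#'   default 0.01.
#' @param dropout_rate Probability that an entry is zeroed; default 0.
#' @param seed Integer seed; default 1.
#' @param mode `"orthogonal"` (default) or `"oblique"`.
#' @return List with
#'   \item{expression}{genes x cells non-negative matrix with gene/cell
#'     ids;}
#'   \item{labels}{integer cluster membership, named by cell id;}
#'   \item{bases}{list of n_genes x subspace_dim orthonormal basis
#'     matrices, one per cluster (the noiseless subspaces).}
#' @examples
#' sim <- simulate_subspace_cells(noise_sd = 0)
#' dim(sim$expression)
#' table(sim$labels)
#' @export
simulate_subspace_cells <- function(n_clusters = 3, cells_per_cluster = 40,
                                    n_genes = 60, subspace_dim = 4,
                                    noise_sd = 0.01, dropout_rate = 0,
                                    seed = 1L,
                                    mode = c("orthogonal", "oblique")) {
  mode <- match.arg(mode)
  stopifnot(n_clusters >= 1, n_genes >= 1, subspace_dim >= 1,
            subspace_dim < n_genes, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (length(cells_per_cluster) == 1L) {
    cells_per_cluster <- rep(cells_per_cluster, n_clusters)
  }
  if (length(cells_per_cluster) != n_clusters) {
    stop("cells_per_cluster must have length 1 or n_clusters")
  }
  stopifnot(all(cells_per_cluster >= 2))
  if (mode == "orthogonal" && n_genes < n_clusters * subspace_dim) {
    stop("orthogonal mode needs n_genes >= n_clusters * subspace_dim (",
         n_clusters * subspace_dim, "), got ", n_genes)
  }
  set.seed(seed)
  N <- sum(cells_per_cluster)
  labels <- rep(seq_len(n_clusters), times = cells_per_cluster)
  G <- matrix(0, n_genes, N)
  bases <- vector("list", n_clusters)

  if (mode == "orthogonal") {
    genes_per_cluster <- n_genes %/% n_clusters
    for (k in seq_len(n_clusters)) {
      block <- ((k - 1L) * genes_per_cluster + 1L):(k * genes_per_cluster)
      B <- matrix(0, n_genes, subspace_dim)
      sub <- split(block, rep(seq_len(subspace_dim), length.out = length(block)))
      for (r in seq_len(subspace_dim)) {
        v <- abs(rnorm(length(sub[[r]])))
        B[sub[[r]], r] <- v / sqrt(sum(v^2))
      }
      coef <- matrix(runif(subspace_dim * cells_per_cluster[k], 0.2, 2),
                     subspace_dim, cells_per_cluster[k])
      G[, labels == k] <- B %*% coef
      bases[[k]] <- B
    }
  } else {
    for (k in seq_len(n_clusters)) {
      B <- qr.Q(qr(matrix(rnorm(n_genes * subspace_dim), n_genes)))
      B <- B[, seq_len(subspace_dim), drop = FALSE]
      coef <- matrix(rnorm(subspace_dim * cells_per_cluster[k], sd = 1),
                     subspace_dim, cells_per_cluster[k])
      G[, labels == k] <- B %*% coef
      bases[[k]] <- B
    }
    G <- G - min(G)   # shift into the non-negative orthant
  }

  if (noise_sd > 0) {
    G <- G + matrix(rnorm(n_genes * N, sd = noise_sd), n_genes, N)
  }
  if (dropout_rate > 0) {
    G[matrix(runif(n_genes * N) < dropout_rate, n_genes, N)] <- 0
  }
  G[G < 0] <- 0

  dimnames(G) <- list(sprintf("gene_%03d", seq_len(n_genes)),
                      sprintf("cell_%03d", seq_len(N)))
  names(labels) <- colnames(G)
  list(expression = G, labels = labels, bases = bases)
}
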