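#' Adaptive penalty weights from positive Pearson correlations
#'
#' Builds the N x N weight matrix W used to scale the per-coefficient L1
#' penalty: `W[i, j] = max(cor(X[, i], X[, j]), 0)` for `i != j`, and 0 on
#' the diagonal. A large weight (high positive correlation) means a small
#' penalty on the corresponding coefficient, so similar cells are cheap to
#' select; non-positive correlations give weight 0, i.e. an infinite
#' penalty, and the solver clamps those coefficients exactly to zero (as it
#' does the diagonal, which the model constrains to zero anyway).
#'
#' Pearson correlation is invariant to positive scaling of columns, so W is
#' the same whether computed on the filtered matrix or its L2-normalized
#' version.
#'
#' @param X Genes-by-cells matrix (>= 2 genes, >= 2 cells), typically the
#'   output of [l2_normalize_columns()].
#' @return N x N symmetric numeric matrix with entries in `[0, 1]`, zero
#'   diagonal, dimnames = cell ids. Zero entries mark hard-zero positions
#'   for the solver.
#' @examples
#' sim <- simulate_subspace_cells(n_clusters = 2, cells_per_cluster = 5,
#'                                n_genes = 12, subspace_dim = 2)
#' W <- compute_weights(l2_normalize_columns(sim$expression))
#' range(W)
#' @export
compute_weights <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L || ncol(X) < 2L) {
    stop("weight computation needs a matrix with >= 2 genes and >= 2 cells")
  }
  sds <- apply(X, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    ids <- if (is.null(colnames(X))) flat else colnames(X)[flat]
    stop("cell(s) with constant expression across genes (Pearson undefined): ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  W <- stats::cor(X)
  W[W < 0] <- 0
  diag(W) <- 0
  # enforce exact symmetry against floating-point asymmetry in cor()
  W <- (W + t(W)) / 2
  W
}
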