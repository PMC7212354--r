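#' Filter uninformative genes
#'
#' Removes genes expressed (value strictly greater than zero) in fewer than
#' 10% of cells. For large datasets the required cell count is capped at
#' 100: a gene is kept iff it is expressed in at least
#' `min(ceiling(0.1 * N), 100)` cells.
#'
#' @param mat Genes-by-cells expression matrix (see [validate_expression()]).
#' @return The matrix restricted to kept genes, cell set and gene order
#'   preserved.
#' @examples
#' sim <- simulate_subspace_cells(n_clusters = 2, cells_per_cluster = 10,
#'                                n_genes = 20, subspace_dim = 2)
#' nrow(filter_genes(sim$expression))
#' @export
filter_genes <- function(mat) {
  validate_expression(mat)
  threshold <- min(ceiling(0.1 * ncol(mat)), 100)
  keep <- rowSums(mat > 0) >= threshold
  if (!any(keep)) {
    stop("no gene is expressed in at least ", threshold,
         " cells; all genes would be removed. Consider looser filtering ",
         "or check that the matrix orientation is genes x cells.")
  }
  mat[keep, , drop = FALSE]
}

#' L2-normalize cell columns
#'
#' Scales every cell column to unit Euclidean norm,
#' `X[i, j] = G[i, j] / sqrt(sum_k G[k, j]^2)`, removing per-cell scale
#' (library size) so that only the direction of the expression profile
#' matters in the subspace model.
#'
#' @param mat Genes-by-cells expression matrix, typically after
#'   [filter_genes()].
#' @return Matrix of the same shape with unit-norm columns.
#' @examples
#' m <- matrix(c(3, 4, 1, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' l2_normalize_columns(m)
#' @export
l2_normalize_columns <- function(mat) {
  validate_expression(mat)
  norms <- sqrt(colSums(mat^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop("cell(s) with no expressed gene after filtering: ",
         paste(utils::head(colnames(mat)[zero], 5L), collapse = ", "))
  }
  sweep(mat, 2L, norms, "/")
}
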