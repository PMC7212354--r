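#' Read a genes-by-cells expression matrix
#'
#' Reads an expression matrix from either a dense delimited file (header row
#' of cell ids, first column of gene ids; comma- or tab-delimited, sniffed
#' from the header line) or a MatrixMarket coordinate file with two sidecar
#' text files giving gene and cell ids, one per line.
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (default; `.mtx` extension selects MatrixMarket),
#'   `"dense"`, or `"mtx"`.
#' @param genes_as Orientation of the stored matrix: `"rows"` (default) if
#'   rows are genes, `"columns"` if the file stores cells as rows. The
#'   returned matrix is always genes x cells.
#' @param genes_file,cells_file Sidecar id files, required for `"mtx"`.
#'   Default: `<path>` with the `.mtx` suffix replaced by `_genes.txt` /
#'   `_cells.txt`.
#' @return A numeric matrix, rows = genes (rownames = gene ids), columns =
#'   cells (colnames = cell ids). All entries non-negative.
#' @examples
#' sim <- simulate_subspace_cells(n_clusters = 2, cells_per_cluster = 5,
#'                                n_genes = 12, subspace_dim = 2)
#' f <- tempfile(fileext = ".csv")
#' write_expression(sim$expression, f)
#' m <- read_expression(f)
#' stopifnot(identical(m, sim$expression))
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"),
                            genes_as = c("rows", "columns"),
                            genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  mat <- if (format == "dense") {
    read_dense_matrix(path)
  } else {
    read_mtx_matrix(path, genes_file, cells_file)
  }
  if (genes_as == "columns") mat <- t(mat)
  validate_expression(mat)
  mat
}

read_dense_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(",", header))) >=
             lengths(regmatches(header, gregexpr("\t", header)))) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed dense matrix file '", path, "': ",
                             conditionMessage(e))
  )
  if (ncol(df) < 2L) {
    stop("malformed dense matrix file '", path,
         "': expected gene id column plus at least one cell column")
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    # locate the first non-numeric cell for a line-numbered message
    col <- bad[1L]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1L]
    stop("malformed dense matrix file '", path, "': non-numeric value at line ",
         row + 1L, ", column '", colnames(vals)[col], "'")
  }
  mat <- as.matrix(vals)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

read_mtx_matrix <- function(path, genes_file, cells_file) {
  if (is.null(genes_file)) genes_file <- sub("\\.mtx$", "_genes.txt", path)
  if (is.null(cells_file)) cells_file <- sub("\\.mtx$", "_cells.txt", path)
  for (f in c(genes_file, cells_file)) {
    if (!file.exists(f)) stop("sidecar id file not found: ", f)
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed MatrixMarket file '", path,
                                         "': ", conditionMessage(e)))
  mat <- as.matrix(m)
  genes <- readLines(genes_file)
  cells <- readLines(cells_file)
  if (length(genes) != nrow(mat)) {
    stop("gene id file '", genes_file, "' has ", length(genes),
         " ids but matrix has ", nrow(mat), " rows")
  }
  if (length(cells) != ncol(mat)) {
    stop("cell id file '", cells_file, "' has ", length(cells),
         " ids but matrix has ", ncol(mat), " columns")
  }
  dimnames(mat) <- list(genes, cells)
  mat
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: writes either a dense delimited file or a
#' MatrixMarket coordinate file plus gene/cell id sidecars.
#'
#' @param mat Genes-by-cells numeric matrix with dimnames.
#' @param path Output file path.
#' @param format `"dense"` (default) or `"mtx"`.
#' @param sep Field separator for dense output (default `","`).
#' @param genes_file,cells_file Sidecar paths for `"mtx"`; defaults as in
#'   [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("dense", "mtx"),
                             sep = ",", genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  validate_expression(mat)
  if (format == "dense") {
    # %.17g guarantees an exact double round-trip
    chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                  dimnames = dimnames(mat))
    df <- data.frame(gene_id = rownames(mat), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    if (is.null(genes_file)) genes_file <- sub("\\.mtx$", "_genes.txt", path)
    if (is.null(cells_file)) cells_file <- sub("\\.mtx$", "_cells.txt", path)
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), genes_file)
    writeLines(colnames(mat), cells_file)
  }
  invisible(path)
}

#' Read cell labels
#'
#' Accepts either a single-column file (one label per line, in cell order)
#' or a two-column delimited file `(cell_id, label)`. With two columns and
#' `cell_ids` given, labels are reordered to match.
#'
#' @param path Label file path.
#' @param cell_ids Optional character vector of cell ids to align to.
#' @return Character vector of labels (named by cell id when available).
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  n_fields <- max(count.fields(path, sep = "\t"),
                  count.fields(path, sep = ","))
  if (n_fields >= 2L) {
    sep <- if (max(count.fields(path, sep = "\t")) >= 2L) "\t" else ","
    df <- read.delim(path, sep = sep, header = FALSE,
                     stringsAsFactors = FALSE)
    # tolerate a header line
    if (!is.null(cell_ids) && !(df[1L, 1L] %in% cell_ids)) {
      df <- df[-1L, , drop = FALSE]
    }
    labels <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
    if (!is.null(cell_ids)) {
      missing <- setdiff(cell_ids, names(labels))
      if (length(missing)) {
        stop("labels missing for cells: ",
             paste(utils::head(missing, 5L), collapse = ", "))
      }
      labels <- labels[cell_ids]
    }
  } else {
    labels <- readLines(path)
    if (!is.null(cell_ids)) {
      if (length(labels) != length(cell_ids)) {
        stop("label file has ", length(labels), " entries but ",
             length(cell_ids), " cells were expected")
      }
      names(labels) <- cell_ids
    }
  }
  if (length(unique(labels)) < 1L) stop("no labels read from ", path)
  labels
}

#' Validate an expression matrix
#'
#' Checks the expression-matrix contract: numeric matrix, at least one gene
#' and two cells, no negative or non-finite entries, unique gene and cell
#' ids.
#'
#' @param mat Matrix to validate.
#' @return `mat`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression must be a numeric matrix (genes x cells)")
  }
  if (nrow(mat) < 1L || ncol(mat) < 2L) {
    stop("expression matrix must have >= 1 gene and >= 2 cells; got ",
         nrow(mat), " x ", ncol(mat))
  }
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("expression matrix contains missing or non-finite values")
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop("expression matrix contains negative values, e.g. ",
         mat[idx[1L], idx[2L]], " at gene ", idx[1L], ", cell ", idx[2L])
  }
  check_unique_ids(rownames(mat), "gene")
  check_unique_ids(colnames(mat), "cell")
  invisible(mat)
}

check_unique_ids <- function(ids, what) {
  if (is.null(ids)) stop("expression matrix lacks ", what, " ids (dimnames)")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, " ids: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(ids)
}
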