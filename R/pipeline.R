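#' Run the full clustering pipeline
#'
#' Orchestrates read (or accept an in-memory matrix) -> gene filtering ->
#' L2 normalization -> adaptive weights -> ADMM solve -> eigengap (when
#' `k = "auto"`) -> spectral clustering -> optional evaluation against
#' reference labels -> optional t-SNE embedding, writing all artifacts and
#' a reproducibility manifest to `out_dir`.
#'
#' Written artifacts: `labels.tsv` (cell_id, cluster), `similarity.tsv`
#' (dense S), `residual_trace.tsv`, `manifest.json` (all parameters,
#' seed, package version, estimated k, convergence), and optionally
#' `metrics.tsv` and `embedding.tsv` (cell_id, x, y). Outputs are
#' deterministic: identical configuration gives byte-identical files.
#'
#' @param input Path to an expression file, or a genes-by-cells matrix.
#' @param format,genes_as Passed to [read_expression()] when `input` is a
#'   path.
#' @param labels Optional reference labels: a path (see [read_labels()]) or
#'   a vector; enables the NMI/ARI report.
#' @param k Number of clusters, or `"auto"` (default) for eigengap
#'   estimation.
#' @param k_max Search cap for the eigengap when `k = "auto"`; default 20.
#' @param lambda,mu,gamma0,tol,max_iter,gamma_update_every Solver settings,
#'   see [ssc_solve()].
#' @param seed Integer seed for k-means restarts and the embedding.
#' @param n_restarts k-means restarts; default 20.
#' @param embed If `TRUE`, also compute and write the t-SNE embedding.
#' @param tsne_iter Iterations for the embedding; default 1000.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `expression`, `normalized`, `weights`,
#'   `fit` (`ssc_fit`), `clustering` (`ssc_clustering`), `k`, `metrics`
#'   (NULL without labels), and `embedding` (NULL unless `embed`).
#' @examples
#' sim <- simulate_subspace_cells(n_clusters = 2, cells_per_cluster = 10,
#'                                n_genes = 24, subspace_dim = 2)
#' res <- run_pipeline(sim$expression, labels = sim$labels, out_dir = NULL)
#' res$k
#' @export
run_pipeline <- function(input, format = "auto", genes_as = "rows",
                         labels = NULL, k = "auto", k_max = 20,
                         lambda = 0.03, mu = 50, gamma0 = 1, tol = 1e-4,
                         max_iter = 200, gamma_update_every = 10,
                         seed = 1L, n_restarts = 20L,
                         embed = FALSE, tsne_iter = 1000L,
                         out_dir = NULL) {
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (is.na(k) || k < 2L) stop("k must be \"auto\" or an integer >= 2")
  } else if (k_max < 2) {
    stop("k = \"auto\" requires k_max >= 2")
  }

  expr <- with_stage("read", {
    if (is.character(input)) {
      read_expression(input, format = format, genes_as = genes_as)
    } else {
      validate_expression(input)
      input
    }
  })
  ref <- with_stage("read", {
    if (is.null(labels)) NULL
    else if (is.character(labels) && length(labels) == 1L &&
             file.exists(labels)) read_labels(labels, colnames(expr))
    else {
      if (length(labels) != ncol(expr)) {
        stop("reference labels length ", length(labels),
             " does not match cell count ", ncol(expr))
      }
      labels
    }
  })

  filtered <- with_stage("filter", filter_genes(expr))
  X <- with_stage("normalize", l2_normalize_columns(filtered))
  W <- with_stage("weights", compute_weights(X))
  fit <- with_stage("solve",
                    ssc_solve(X, W, lambda = lambda, mu = mu,
                              gamma0 = gamma0, tol = tol,
                              max_iter = max_iter,
                              gamma_update_every = gamma_update_every))
  A <- with_stage("cluster", build_affinity(fit$S))
  k_used <- if (identical(k, "auto")) {
    with_stage("cluster", estimate_k_eigengap(A, k_max = k_max))
  } else {
    k
  }
  clustering <- with_stage("cluster",
                           spectral_cluster(A, k = k_used, seed = seed,
                                            n_restarts = n_restarts))
  metrics <- if (!is.null(ref)) {
    with_stage("evaluate",
               list(nmi = nmi(ref, clustering$labels),
                    ari = ari(ref, clustering$labels)))
  }
  embedding <- if (embed) {
    with_stage("embed", tsne_embed(similarity_to_p(fit$S), seed = seed,
                                   n_iter = tsne_iter))
  }

  if (!is.null(out_dir)) {
    with_stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.table(data.frame(cell_id = colnames(expr),
                             cluster = unname(clustering$labels)),
                  file.path(out_dir, "labels.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(data.frame(cell_id = rownames(fit$S),
                             round(fit$S, 12), check.names = FALSE),
                  file.path(out_dir, "similarity.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(fit$residuals, file.path(out_dir, "residual_trace.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      if (!is.null(metrics)) {
        write.table(data.frame(metric = c("nmi", "ari"),
                               value = c(metrics$nmi, metrics$ari)),
                    file.path(out_dir, "metrics.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
      if (!is.null(embedding)) {
        write.table(data.frame(cell_id = colnames(expr),
                               x = embedding$coords[, 1L],
                               y = embedding$coords[, 2L]),
                    file.path(out_dir, "embedding.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
      manifest <- list(
        input = if (is.character(input)) input else "<in-memory matrix>",
        format = format, genes_as = genes_as,
        n_genes = nrow(expr), n_cells = ncol(expr),
        n_genes_kept = nrow(filtered),
        k = if (identical(k, "auto")) "auto" else k,
        k_estimated = k_used, k_max = k_max,
        lambda = lambda, mu = mu, gamma0 = gamma0, tol = tol,
        max_iter = max_iter, gamma_update_every = gamma_update_every,
        seed = seed, n_restarts = n_restarts,
        converged = fit$converged, n_iter = fit$n_iter,
        embed = embed, tsne_iter = if (embed) tsne_iter else NULL,
        package_version = as.character(utils::packageVersion("cellSSC")))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }

  invisible(list(expression = expr, normalized = X, weights = W, fit = fit,
                 clustering = clustering, k = k_used, metrics = metrics,
                 embedding = embedding))
}

# Rethrow any stage error tagged with the stage name.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      stop("in stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
}
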