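Package: cellSSC
Title: Adaptive Sparse Subspace Clustering for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell types from single-cell RNA-seq expression
    matrices by learning a sparse cell-cell similarity matrix under the
    subspace assumption: cells of the same type lie in a common
    low-dimensional linear subspace of gene space, so each cell can be
    written as a sparse linear combination of its peers. The
    self-expressive coefficients are estimated by an alternating direction
    method of multipliers (ADMM) with a data-driven, Pearson-correlation
    weighted L1 penalty, then clustered by normalized-Laplacian spectral
    clustering with eigengap model selection. Includes clustering
    evaluation (NMI, ARI), a similarity-driven t-SNE embedding, and a
    subspace-structured synthetic data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
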