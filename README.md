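# cellSSC

Adaptive sparse subspace clustering for single-cell RNA-seq cell-type
identification.

## The problem and the model

Identifying cell types from a scRNA-seq expression matrix is, at its core,
a clustering problem on very noisy, very high-dimensional profiles, and
the quality of the result is dominated by the quality of the cell–cell
similarity measure. `cellSSC` learns that similarity instead of computing
it from a fixed kernel, under the *subspace assumption*: cells of one type
lie in a common low-dimensional linear subspace of gene space, so each
cell can be written as a linear combination of the other cells of its
type (*self-expressiveness*). With X the gene-filtered, column
L2-normalized expression matrix (genes × cells), the package solves

```
min_C  ½ ‖X − XC‖²_F + λ |J ⊘ W|₁    s.t.  diag(C) = 0,  C = J
```

by ADMM, where ⊘ is elementwise division and W is a data-driven weight
matrix: `W[i,j] = max(pearson(X_i, X_j), 0)`. Highly correlated cell pairs
are penalized little; non-positively correlated pairs get weight 0 — an
infinite penalty that clamps their coefficient to exactly zero. This
adaptive reweighting keeps each cell's nearest neighbours without fixing a
neighbourhood size by hand and makes the result far less sensitive to λ
than plain sparse subspace clustering.

The converged coefficients give a symmetric similarity `S = Cᵀ + C`, which
feeds normalized-Laplacian spectral clustering (`L = I − D^{-1/2} A
D^{-1/2}`, A = |S|), with the number of clusters estimated by the eigengap
heuristic when not supplied. The same S can drive a modified t-SNE (its
affinities replace the usual Gaussian-kernel probabilities) for 2-D
visualization, and clusterings are scored against reference labels with
NMI and ARI.

## Worked example

The package ships a generator for subspace-structured synthetic data (3
clusters of 40 cells in mutually orthogonal dim-4 subspaces of a 60-gene
space by default), so the whole pipeline can be exercised without any
download:

```r
library(cellSSC)
sim <- simulate_subspace_cells(noise_sd = 0.01, seed = 1)
X   <- l2_normalize_columns(filter_genes(sim$expression))
W   <- compute_weights(X)
fit <- ssc_solve(X, W, lambda = 0.03)
fit
#> Adaptive sparse subspace fit
#>   cells: 120   lambda: 0.03
#>    iteration cap reached after 200 iterations (max|C - J| = 0.000281 )
#>   off-diagonal sparsity of C: 0.0431

A <- build_affinity(fit$S)
estimate_k_eigengap(A)
#> [1] 3
cl <- spectral_cluster(A, k = 3, seed = 1)
cl
#> Spectral clustering: 120 cells into 3 clusters
#> cluster
#>  1  2  3
#> 40 40 40
c(nmi = nmi(sim$labels, cl$labels), ari = ari(sim$labels, cl$labels))
#> nmi ari
#>   1   1
```

The solver report says the run used its full 200-iteration budget with the
coefficient/auxiliary gap at 2.8e-4 — normal on noisy data, and harmless
here: the learned similarity still has its mass inside the true blocks, so
the eigengap finds k = 3 and the clustering matches the planted labels
exactly (NMI = ARI = 1). The sparsity 0.043 sits inside the 0.02–0.05 band
used by [`select_lambda()`] for data-driven λ selection.

`run_pipeline()` wraps all of the above (plus optional t-SNE embedding and
metric report) and writes labels, similarity, residual trace and a
reproducibility manifest to an output directory. The same pipeline is
available from a shell via the thin CLI:

```sh
Rscript inst/cli/cellssc.R cluster --input expr.csv --labels labels.tsv --out-dir out/
Rscript inst/cli/cellssc.R simulate --out-prefix sim   # writes a test dataset
```

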