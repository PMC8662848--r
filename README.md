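# snsvd — sparse network-regularized SVD for gene module discovery

Genes acting in the same biological process tend to be co-expressed across
a subset of samples *and* connected in protein–protein interaction (PPI)
networks. Plain sparse-SVD biclustering finds the first pattern but ignores
the second, which often yields modules that are hard to interpret
biologically. `snsvd` factorizes a genes × samples expression matrix
`X ∈ R^{p×n}` into sparse rank-one components `d·uvᵀ` while steering the
gene loadings `u` toward the structure of a prior gene interaction network:

```
minimize   −uᵀXv + λ‖u‖₁ + (σ/2)·uᵀLu
subject to ‖u‖₂ = ‖v‖₂ = 1,  ‖v‖₀ ≤ k_v
```

`L` is the normalized graph Laplacian of the network, so `uᵀLu` penalizes
loading differences across interaction edges; `λ` (or a target gene count)
controls gene sparsity and the L0 bound `k_v` fixes the number of samples
per module. The solver alternates a network-smoothed soft-thresholding
coordinate descent on `u` with an exact top-`k_v` projection on `v`;
further factors come from deflation with random restarts. The package is
aimed at computational biologists mining expression compendia (cell-line
panels, tumour cohorts) for interpretable co-expression modules, and
includes the companion differential co-expression pipeline for matched
two-condition miRNA/mRNA data.

## Worked example

```r
library(snsvd)
set.seed(1)

# a 60x30 rank-one block (15 genes x 15 samples) plus noise, with a
# planted-partition prior network over the genes
sim <- simulate_snsvd_data(p = 60, n = 30, support = 15, gamma = 0.05)

fit <- snsvd(sim$X, sim$network, k = 1, sigma = 0.5, kv = 15,
             nnz_u = 15, seed = 1)
summary(fit)
#> Sparse network-regularized SVD: factor summary
#>  factor        d nnz_u nnz_v iterations converged
#>       1 15.00972    15    15          4      TRUE
#> residual Frobenius norm: 2.099 (13.8% of total)

mods <- extract_modules(fit, threshold = 0)
interaction_enrichment(sim$network, mods[[1]])$score   # 8.2 (> 1.3: dense)
module_modularity(sim$X, mods[[1]])                    # 0.215

score_recovery(fit$u[, 1], fit$v[, 1], sim$u_support, sim$v_support)
#>   vector sensitivity specificity accuracy
#> 1      u           1           1        1
#> 2      v           1           1        1
```

The factor carries exactly the requested 15 genes and 15 samples and
recovers the planted supports perfectly; the singular value `d ≈ 15`
matches the planted block (`‖u‖·‖v‖ = √15·√15`). The interaction
enrichment score is `−log10` of a right-tailed hypergeometric p-value for
the module's induced edge count — values above 1.3 (p < 0.05) mean the
module's genes are significantly inter-connected. Modularity is the mean
absolute pairwise Pearson correlation of the module's genes over the
module's samples.

Other entry points: `tune_lambda()` (λ from a gene-count target),
`cv_sigma()` (σ by 5-fold entry-holdout cross-validation),
`run_benchmark()` (simulation comparison against the σ = 0 sparse SVD),
`differential_matrix()` / `diff_coexpr_modules()` / `adpcc_test()` (the
two-condition differential miRNA–gene pipeline), and a thin command-line
wrapper at `inst/cli/snsvd.R` with `run`, `simulate`, `cv`, `benchmark`,
`diffcoexpr` and `evaluate` subcommands. The methods vignette
(`vignettes/snsvd-methods.Rmd`) documents the model, the numerical design
choices and the simulation conditions.

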