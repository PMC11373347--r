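# hcrsim

Hierarchical cluster-wise PCA reconstruction and simulation of omics
correlation structure.

## What it is for

High-dimensional expression data (bulk or single-cell transcriptomics after
preprocessing) has a hierarchical correlation structure: co-expressed gene
modules, sub-modules within them, and a background of essentially
uncorrelated variables. People who benchmark feature-selection, clustering
or other ML protocols on such data need synthetic datasets that reproduce
this structure — with known ground truth, and statistically independent of
any real cohort. Full-covariance simulation (Cholesky on the estimated
covariance) fails outright when samples ≪ variables.

`hcrsim` fits a **hierarchical clustering-based decomposition**: variables
are partitioned by Markov clustering (MCL) of the squared-Pearson
similarity graph (small clusters become a noise subset \(C_0\)), each
cluster is summarised by its leading \(k\) principal components, and
clusters with unexplained variance are recursively subdivided by
complete-linkage clustering of residual distances
\(d_{ij} = 1 - \mathrm{cor}(E_i, E_j)^2\), with the cut chosen by maximal
normalized entropy. Each variable ends up a linear combination of at most
\(g \times k\) components, and the per-variable variance ledger

\[
\mathrm{Var}(X_i) = \mathrm{Var}(X_i^R) + \mathrm{Var}(E_i)
\]

holds exactly, so the fraction of variance explained
\(V_E = V_{X^R}/V_X\) is tracked without re-touching the data.

The fitted decomposition drives a **simulator**: synthetic component scores
are drawn with the same correlation matrix as the real components (normal
marginals, or metalog-fitted marginals through a Gaussian copula),
recombined with the fitted loadings, and topped up with independent
**variance-matching noise** so every simulated variable has the variance of
its real counterpart. The output is independent of the original samples but
reproduces its correlation matrix and weighted-network topology (degree,
clustering coefficient, topological overlap).

## Worked example

```r
library(hcrsim)

# planted two-level benchmark: 3 parent modules, 11 child modules,
# signal fraction 0.7, 10 pure-noise variables, n = 500
g <- generate_hierarchical_blocks(default_block_spec(), seed = 42)

model <- hcr_fit(g$X, f_E = 0.85, k = 5, g_max = 2, seed = 42)
model
#> Hierarchical cluster-wise PCA decomposition
#>   206 variables x 500 samples, 2 level(s), k = 5
#>   clusters per level: 3, 16; noise subset: 10 variables
#>   components: 95 total, at most 10 per variable
#>   variance explained V_E = 0.8227 (target f_E = 0.85)

sim <- hcs_simulate(model, variant = "normal", seed = 42)
m <- compare_structures(g$X, sim$values)
sprintf("r_max = %.4f  r_avg = %.5f  cr_rmse = %.4f", m$r_max, m$r_avg, m$cr_rmse)
#> "r_max = 0.0376  r_avg = 0.00211  cr_rmse = 0.0485"

ground_truth_ari(model$levels[[1]]$labels, g$truth$level1)
#> 1
```

Reading the numbers: the adaptive stage recovers the three planted parent
modules exactly (ARI 1) and sends the 10 unstructured variables to the
noise subset; two levels of five components each explain 82% of the total
variance. The simulated dataset's squared correlations with the *original*
samples stay at the noise floor (`r_max` 0.038, `r_avg` ≈ 1/(n−1) ≈ 0.002 —
nothing of the original samples leaks through), while the RMSE between the
two correlation matrices is below 0.05 — the structure, not the samples, is
reproduced.

Other entry points: `reconstruct()` (low-rank reconstruction of the
original data), `add_variance_matching_noise()`,
`adjacency()` / `weighted_degree()` / `clustering_coefficient()` / `tom()` /
`network_dendrogram()` (weighted-network topology),
`topology_summary()` (distributions + KS comparison),
`metalog_fit()` / `metalog_sample()` (quantile-parameterized marginals),
`write_hcd_model()` / `read_hcd_model()` (model archives),
`run_pipeline()` (end-to-end run with manifest), and a thin command-line
front end in `inst/cli/hcs.R` with subcommands
`fit` / `reconstruct` / `simulate` / `evaluate` / `synth` / `run`.

See the methods vignette (`vignettes/hcs-methods.Rmd`) for the model,
the tunable parameters, and the reasoning behind the design choices.

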