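Package: hcrsim
Title: Hierarchical Clustering-Based Reconstruction and Simulation of
    Omics Correlation Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the correlation structure of high-dimensional omics
    expression matrices by a hierarchical, cluster-wise principal
    component decomposition (HCR): variables are grouped by Markov
    clustering of squared Pearson correlations, each cluster is
    summarised by a few principal components, and residual structure is
    captured by recursive subdivision with an entropy-guided separator.
    The fitted decomposition drives two simulators (HCS) that generate
    new, independent datasets whose correlation structure and weighted
    network topology (degree, clustering coefficient, topological
    overlap) match the reference data, with either normal or
    metalog-fitted marginal distributions of the latent components and a
    variance-matching noise step.  Includes a planted-hierarchy
    expression-like data generator for benchmarking feature-selection
    and clustering methods against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
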