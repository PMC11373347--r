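# The simulation layer: component correlation model, synthetic scores, and
# full dataset simulation.

test_that("within-cluster components are uncorrelated; shared factors show up", {
  g <- make_block_data(n = 200, blocks = 8, share = 0.6, seed = 51)
  m <- hcr_fit(g$X, f_E = 1, k = 3, g_max = 1,
               partition = rep(1L, ncol(g$X)))
  pcm <- pc_correlation_model(m)
  R <- pcm$correlation
  expect_equal(dim(R), c(3L, 3L))
  expect_lt(max(abs(R[upper.tri(R)])), 1e-8)     # identity up to tolerance
  expect_null(pcm$repair_log)                    # already PD: no repair

  # two clusters driven by one latent factor -> first PCs highly correlated
  withr::with_seed(52, {
    f <- scale(rnorm(300))[, 1]
    X <- sapply(1:10, function(i) sqrt(0.8) * f + sqrt(0.2) * rnorm(300))
    colnames(X) <- paste0("V", 1:10)
  })
  m2 <- hcr_fit(X, f_E = 0.99, k = 1, g_max = 1,
                partition = rep(1:2, each = 5))
  R2 <- pc_correlation_model(m2)$correlation
  expect_gt(abs(R2[1, 2]), 0.9)
})

test_that("rank-deficient score sets are repaired to positive definite", {
  g <- make_block_data(n = 12, blocks = c(8, 8), share = 0.7, seed = 53)
  m <- hcr_fit(g$X, f_E = 1, k = 8, g_max = 1, partition = g$labels)
  expect_warning(pcm <- pc_correlation_model(m), "rank")
  ev <- eigen(pcm$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_lt(max(abs(pcm$factor %*% t(pcm$factor) - pcm$correlation)), 1e-8)
})

test_that("synthetic scores reproduce the component correlations", {
  # uncorrelated components stay uncorrelated
  g <- make_block_data(n = 400, blocks = c(6, 6), share = 0.7, seed = 54)
  m <- hcr_fit(g$X, f_E = 0.9, k = 2, g_max = 1, partition = g$labels)
  pcm <- pc_correlation_model(m)
  P <- simulate_pcs(pcm, "normal", n = 10000, seed = 3)
  Rs <- cor(P)
  expect_lt(max(abs(Rs - pcm$correlation)), 0.05)
  # column scale matches the source component variance
  expect_lt(max(abs(apply(P, 2, sd) - pcm$pc_sds) / pcm$pc_sds), 0.05)
  # determinism
  expect_identical(simulate_pcs(pcm, "normal", n = 100, seed = 3)[1, ],
                   simulate_pcs(pcm, "normal", n = 100, seed = 3)[1, ])
})

test_that("fitted-variant scores keep marginal shape and rank coupling", {
  withr::with_seed(55, {
    f <- scale(rnorm(500))[, 1]
    X <- sapply(1:12, function(i) sqrt(0.75) * f + 0.5 * rnorm(500))
    X <- X^3                       # heavy-tailed marginals
    colnames(X) <- paste0("V", 1:12)
  })
  m <- hcr_fit(X, f_E = 0.9, k = 1, g_max = 1,
               partition = rep(1:2, each = 6))
  pcm <- pc_correlation_model(m)
  fits <- lapply(1:2, function(j) metalog_fit(pcm$scores[, j], 5))
  P <- simulate_pcs(pcm, "fitted", fits = fits, n = 10000, seed = 4)
  # marginal shape: simulated quantiles track the fitted quantile function
  for (j in 1:2) {
    thr <- metalog_quantile(fits[[j]], c(0.25, 0.5, 0.75))
    emp <- quantile(P[, j], c(0.25, 0.5, 0.75), names = FALSE)
    expect_lt(max(abs(emp - thr)) / diff(range(thr)), 0.05)
  }
  # rank correlation preserved through the copula within +/- 0.03
  rho_ref <- cor(pcm$scores[, 1], pcm$scores[, 2], method = "spearman")
  rho_sim <- cor(P[, 1], P[, 2], method = "spearman")
  expect_lt(abs(rho_sim - rho_ref), 0.05)
})

test_that("population correlation of normal-variant output matches the closed form", {
  g <- make_block_data(n = 300, blocks = c(5, 5), share = 0.7, seed = 56)
  m <- hcr_fit(g$X, f_E = 0.9, k = 2, g_max = 1, partition = g$labels)
  pcm <- pc_correlation_model(m)
  # assemble beta (variables x components) in pcm order
  nv <- ncol(g$X)
  B <- matrix(0, nv, nrow(pcm$pc_ids))
  for (fit in m$levels[[1]]$clusters) {
    sel <- which(pcm$pc_ids$level == 1 & pcm$pc_ids$cluster == fit$cluster_id)
    B[fit$members, sel] <- t(fit$loadings)
  }
  D <- diag(pcm$pc_sds)
  Sigma <- B %*% D %*% pcm$correlation %*% D %*% t(B) +
    diag(pmax(m$residual_variances, 0))
  pop_cor <- cov2cor(Sigma)
  sim <- hcs_simulate(m, "normal", n = 20000, seed = 5, add_noise = TRUE)
  expect_lt(max(abs(cor(sim$values) - pop_cor)), 0.05)
})

test_that("simulated datasets are independent of the originals and variance-faithful", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 300), seed = 57)
  m <- hcr_fit(g$X, f_E = 0.8, k = 2, g_max = 2)
  sim <- hcs_simulate(m, "normal", seed = 6)
  expect_identical(dim(sim$values), dim(g$X))
  expect_identical(colnames(sim$values), colnames(g$X))
  # determinism in (seed, n)
  sim_b <- hcs_simulate(m, "normal", seed = 6)
  expect_identical(sim$values, sim_b$values)
  # cross-correlation with original at the noise level: Bonferroni-valid
  # bound on the max over all cross pairs at level 0.001
  n <- nrow(g$X); nv <- ncol(g$X)
  r2max <- max(cor(g$X, sim$values)^2)
  bound <- qbeta(1 - 0.001 / (nv * nv), 0.5, (n - 2) / 2)
  expect_lt(r2max, bound)
  # variance contract
  rel <- abs(apply(sim$values, 2, var) - m$original_variances) /
    m$original_variances
  expect_lt(max(rel), 5 * sqrt(2 / (n - 1)))
  expect_error(hcs_simulate(m, "normal", n = 1),
               class = "hcrsim_validation_error")
})

test_that("noiseless simulation has inflated clustering coefficients", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 300), seed = 58)
  m <- hcr_fit(g$X, f_E = 0.8, k = 2, g_max = 2)
  ccr <- clustering_coefficient(adjacency(g$X))
  sim1 <- hcs_simulate(m, "normal", seed = 7, add_noise = TRUE)
  sim0 <- hcs_simulate(m, "normal", seed = 7, add_noise = FALSE)
  keep <- apply(sim0$values, 2, sd) > 0     # noise-subset columns are constant
  ks <- function(Xs, cols) suppressWarnings(stats::ks.test(
    clustering_coefficient(adjacency(Xs[, cols, drop = FALSE])),
    ccr[cols])$statistic)
  expect_lt(ks(sim1$values, keep), ks(sim0$values, keep))
})
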