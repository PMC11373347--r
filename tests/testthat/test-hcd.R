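# Cluster-wise PCA, the hierarchical fit, reconstruction and the variance
# ledger.

test_that("cluster_pca handles single members and rank-1 clusters", {
  x <- withr::with_seed(21, rnorm(30))
  f1 <- cluster_pca(matrix(x, ncol = 1), k = 5)
  expect_equal(f1$n_pcs, 1)
  expect_equal(abs(f1$scores[, 1]), abs(x - mean(x)))
  expect_equal(abs(f1$loadings[1, 1]), 1)

  X2 <- cbind(x, -x)
  f2 <- cluster_pca(X2, k = 1)
  expect_equal(sum(f2$pc_variances), sum(col_vars <- apply(X2, 2, var)),
               tolerance = 1e-10)   # one PC carries all cluster variance
})

test_that("cluster_pca explained variances match an eigendecomposition", {
  X <- withr::with_seed(22, matrix(rnorm(180), 30, 6))
  f <- cluster_pca(X, k = 3)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(f$pc_variances, ev[1:3], tolerance = 1e-10)
  expect_true(all(diff(f$pc_variances) <= 1e-12))
  # score columns mutually orthogonal
  G <- crossprod(f$scores)
  expect_lt(max(abs(G[upper.tri(G)])) /
              max(sqrt(diag(G) %o% diag(G))), 1e-8)
  # sign convention: largest-|loading| coefficient positive
  for (p in 1:3)
    expect_gt(f$loadings[p, which.max(abs(f$loadings[p, ]))], 0)
  expect_error(cluster_pca(matrix(1, 10, 2), k = 1),
               class = "hcrsim_validation_error")
})

test_that("noiseless rank-1 blocks are explained exactly at one level", {
  g <- make_rank1_data(n = 60, blocks = c(4, 5, 3))
  m <- hcr_fit(g$X, f_E = 0.99, k = 1, g_max = 1, partition = g$labels)
  expect_equal(variance_explained(m), 1, tolerance = 1e-8)
  expect_length(m$levels, 1)
  expect_lt(max(abs(reconstruct(m) - g$X)), 1e-8)
})

test_that("full-order reconstruction reproduces the data exactly", {
  g <- make_block_data(n = 50, blocks = c(6, 5, 4), share = 0.6, seed = 23)
  m <- hcr_fit(g$X, f_E = 1, k = 6, g_max = 1, partition = g$labels)
  expect_lt(max(abs(reconstruct(m) - g$X)), 1e-8)
  expect_equal(variance_explained(m), 1, tolerance = 1e-10)
})

test_that("an unreachable variance target raises the specific error", {
  g <- make_block_data(n = 120, blocks = c(8, 8), share = 0.8, seed = 24)
  nv <- ncol(g$X)
  noisy <- cbind(g$X,
                 withr::with_seed(25,
                   matrix(rnorm(120 * 11, sd = sqrt(1.0)), 120, 11,
                          dimnames = list(NULL, paste0("N", 1:11)))))
  labels <- c(g$labels, rep(0L, 11))
  # noise subset holds ~40% of total variance; f_E = 0.9 is unreachable
  err <- expect_error(
    hcr_fit(noisy, f_E = 0.9, k = 2, g_max = 1, partition = labels),
    class = "hcrsim_insufficient_variance_error")
  expect_gt(err$required, err$available)
})

test_that("the variance ledger holds at every level of a two-level fit", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 200), seed = 31)
  m <- hcr_fit(g$X, f_E = 0.8, k = 2, g_max = 2)
  ov <- m$original_variances
  for (lev in seq_along(m$levels)) {
    XR <- reconstruct(m, up_to_level = lev)
    E <- g$X - XR
    lhs <- ov
    rhs <- apply(XR, 2, var) + apply(E, 2, var)
    expect_lt(max(abs(lhs - rhs) / lhs), 1e-8)
  }
  # level-1 reconstruction explains strictly less variance than both levels
  v1 <- sum(apply(reconstruct(m, 1), 2, var))
  v2 <- sum(apply(reconstruct(m), 2, var))
  expect_lt(v1, v2)
  expect_error(reconstruct(m, up_to_level = 5),
               class = "hcrsim_validation_error")
})

test_that("within-cluster variance equals the sum of all PC variances", {
  # locality of the variance decomposition, full component retention
  g <- make_block_data(n = 40, blocks = c(5, 6), share = 0.5, seed = 26)
  m <- hcr_fit(g$X, f_E = 1, k = 10, g_max = 1, partition = g$labels)
  for (fit in m$levels[[1]]$clusters) {
    V_C <- sum(apply(g$X[, fit$members, drop = FALSE], 2, var))
    expect_equal(sum(fit$pc_variances), V_C, tolerance = 1e-8)
  }
})

test_that("variance explained equals the residual-variance identity", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 150), seed = 32)
  m <- hcr_fit(g$X, f_E = 0.8, k = 1, g_max = 2)
  expect_equal(variance_explained(m),
               1 - sum(m$residual_variances) / sum(m$original_variances),
               tolerance = 1e-10)
  XR <- reconstruct(m)
  expect_equal(variance_explained(m),
               sum(apply(XR, 2, var)) / sum(m$original_variances),
               tolerance = 1e-8)
})

test_that("V_E is monotone in k and in the number of levels", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 200), seed = 33)
  ve <- vapply(1:3, function(k)
    variance_explained(hcr_fit(g$X, f_E = 0.85, k = k, g_max = 1)),
    numeric(1))
  expect_true(all(diff(ve) > 0))
  m2 <- hcr_fit(g$X, f_E = 0.85, k = 1, g_max = 2)
  expect_true(all(diff(m2$v_explained_trace) >= 0))
})

test_that("partitions are nested across levels", {
  g <- generate_hierarchical_blocks(two_level_spec(n_samples = 200), seed = 34)
  m <- hcr_fit(g$X, f_E = 0.85, k = 1, g_max = 3)
  for (lev in seq_along(m$levels)[-1]) {
    child <- m$levels[[lev]]$labels
    parent <- m$levels[[lev - 1]]$labels
    for (cid in unique(child[child > 0]))
      expect_length(unique(parent[child == cid]), 1)
  }
})

test_that("reconstruction is equivariant under variable permutation", {
  g <- make_block_data(n = 60, blocks = c(5, 5), share = 0.7, seed = 27)
  m <- hcr_fit(g$X, f_E = 0.9, k = 2, g_max = 1, partition = g$labels)
  perm <- withr::with_seed(28, sample(ncol(g$X)))
  mp <- hcr_fit(g$X[, perm], f_E = 0.9, k = 2, g_max = 1,
                partition = g$labels[perm])
  expect_lt(max(abs(reconstruct(mp) - reconstruct(m)[, perm])), 1e-8)
})

test_that("variance-matching noise restores per-variable variance", {
  g <- make_block_data(n = 10000, blocks = c(4, 4), share = 0.5, seed = 29)
  m <- hcr_fit(g$X, f_E = 0.6, k = 1, g_max = 1, partition = g$labels)
  XR <- reconstruct(m)
  noisy <- add_variance_matching_noise(XR, m, seed = 30)
  rel <- abs(apply(noisy, 2, var) - m$original_variances) /
    m$original_variances
  expect_lt(max(rel), 0.05)   # ~ Var * sqrt(2/(n-1)) sampling bound
  # same seed -> identical; different seed -> different draw
  expect_identical(add_variance_matching_noise(XR, m, seed = 30), noisy)
  expect_false(identical(add_variance_matching_noise(XR, m, seed = 31),
                         noisy))
  # fully explained variable stays untouched
  m0 <- m; m0$residual_variances[] <- 0
  expect_identical(add_variance_matching_noise(XR, m0, seed = 1), XR)
})

test_that("component accounting matches the cluster layout", {
  g <- make_block_data(n = 30, blocks = c(6, 6), share = 0.6, seed = 35)
  m <- hcr_fit(g$X, f_E = 1, k = 2, g_max = 1,
               partition = rep(1L, ncol(g$X)))
  pcs <- pc_count_summary(m)
  expect_identical(pcs$total_pcs, 2L)
  expect_identical(pcs$max_pcs_per_variable, 2L)
})

test_that("fixed nested partitions are validated", {
  lev1 <- c(1L, 1L, 2L, 2L)
  bad2 <- c(1L, 2L, 2L, 3L)   # child 2 spans both parents
  X <- make_block_data(n = 30, blocks = c(2, 2), seed = 36)$X
  expect_error(hcr_fit(X, f_E = 0.9, k = 1, partition = list(lev1, bad2)),
               class = "hcrsim_validation_error")
})
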