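# Fixtures built in code; everything is deterministic given the seed.

# Planted one-level block data: `blocks` variables per block share one
# standardized factor with variance share `share`; remainder idiosyncratic.
make_block_data <- function(n = 100, blocks = c(5, 5, 5), share = 0.8,
                            seed = 1) {
  withr::with_seed(seed, {
    cols <- list(); labels <- integer()
    for (b in seq_along(blocks)) {
      f <- scale(rnorm(n))[, 1]
      for (v in seq_len(blocks[b])) {
        cols[[length(cols) + 1L]] <-
          sqrt(share) * f + sqrt(1 - share) * rnorm(n)
        labels <- c(labels, b)
      }
    }
    X <- do.call(cbind, cols)
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    rownames(X) <- paste0("S", seq_len(nrow(X)))
    list(X = X, labels = labels)
  })
}

# Exactly rank-1 per block: no idiosyncratic noise at all.
make_rank1_data <- function(n = 60, blocks = c(4, 5, 3), seed = 2) {
  withr::with_seed(seed, {
    cols <- list(); labels <- integer()
    for (b in seq_along(blocks)) {
      f <- rnorm(n)
      for (v in seq_len(blocks[b])) {
        cols[[length(cols) + 1L]] <- runif(1, 0.5, 2) * f + rnorm(1)
        labels <- c(labels, b)
      }
    }
    X <- do.call(cbind, cols)
    colnames(X) <- paste0("V", seq_len(ncol(X)))
    list(X = X, labels = labels)
  })
}

# The standard two-level benchmark spec used across tests: 3 parents,
# 11 children, shares 0.4/0.3 (signal fraction 0.7).
two_level_spec <- function(n_samples = 500, n_noise = 10) {
  sp <- default_block_spec(n_samples = n_samples)
  sp$n_noise_variables <- as.integer(n_noise)
  sp
}

expect_partition_equal <- function(a, b) {
  expect_equal(ground_truth_ari(a, b), 1)
}
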