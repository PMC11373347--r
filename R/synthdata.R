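# Planted-hierarchy expression-like data generator.
#
# Each variable in child block c of parent block p is
#   x = sqrt(ps) * F_p + sqrt(cs) * F_pc + sqrt(1 - ps - cs) * eps,
# with the parent and child factors standardized to unit sample variance, so
# the planted signal fraction of the variable is ps + cs.  Noise variables
# are pure idiosyncratic draws.  This is the structure the decomposition
# assumes: highly correlated groups that are accurately described by a small
# number of latent factors, nested two levels deep.

#' Specify a planted hierarchical block structure
#'
#' @param parent_blocks List of parent block specs; each a list with
#'   `parent_share` (fraction of variance from the parent factor) and
#'   `children`, a list of `list(size =, child_share =)` entries.  A parent
#'   without children is a single child of itself.
#' @param n_noise_variables Number of pure-noise variables appended.
#' @param n_samples Number of samples to draw.
#' @param marginal Marginal shape: `"normal"`, `"lognormal"` (exponential
#'   transform) or `"mixture"` (a monotone bimodalizing transform).  The
#'   transform is monotone, so the rank correlation structure is exact while
#'   Pearson correlations are perturbed.
#' @param cross_parent_correlation Pairwise correlation between parent
#'   factors, in `[0, 1)`.
#' @return A `block_spec` list.
#' @export
block_spec <- function(parent_blocks, n_noise_variables = 0L,
                       n_samples = 500L,
                       marginal = c("normal", "lognormal", "mixture"),
                       cross_parent_correlation = 0) {
  marginal <- match.arg(marginal)
  for (pb in parent_blocks) {
    ps <- pb$parent_share
    if (is.null(ps) || ps < 0 || ps > 1)
      stop_hcrsim("parent_share must be in [0, 1]", "hcrsim_validation_error")
    for (ch in pb$children) {
      if (is.null(ch$size) || ch$size < 1)
        stop_hcrsim("child sizes must be >= 1", "hcrsim_validation_error")
      cs <- ch$child_share
      if (is.null(cs) || cs < 0 || ps + cs > 1)
        stop_hcrsim("parent_share + child_share must be <= 1",
                    "hcrsim_validation_error")
    }
  }
  if (cross_parent_correlation < 0 || cross_parent_correlation >= 1)
    stop_hcrsim("cross_parent_correlation must be in [0, 1)",
                "hcrsim_validation_error")
  structure(list(parent_blocks = parent_blocks,
                 n_noise_variables = as.integer(n_noise_variables),
                 n_samples = as.integer(n_samples),
                 marginal = marginal,
                 cross_parent_correlation = cross_parent_correlation),
            class = "block_spec")
}

#' Default two-level benchmark structure
#'
#' Three parent blocks holding 3, 4 and 4 child blocks (11 children in
#' total, mirroring a realistic two-level module hierarchy), parent factors
#' carrying 40% and child factors 30% of each variable's variance (signal
#' fraction 0.7), plus 10 pure-noise variables.  Child block sizes
#' (14-25 variables) are on the scale of real co-expression modules.
#'
#' @param n_samples Number of samples, default 500.
#' @param parent_share,child_share Variance shares, defaults 0.4 and 0.3.
#' @param marginal Passed to [block_spec()].
#' @return A `block_spec`.
#' @export
default_block_spec <- function(n_samples = 500L, parent_share = 0.4,
                               child_share = 0.3, marginal = "normal") {
  kids <- function(sizes)
    lapply(sizes, function(s) list(size = s, child_share = child_share))
  block_spec(
    parent_blocks = list(
      list(parent_share = parent_share, children = kids(c(25L, 20L, 20L))),
      list(parent_share = parent_share, children = kids(c(20L, 18L, 16L, 16L))),
      list(parent_share = parent_share, children = kids(c(18L, 15L, 14L, 14L)))),
    n_noise_variables = 10L,
    n_samples = n_samples,
    marginal = marginal)
}

#' Generate expression-like data with planted hierarchical correlation
#'
#' @param spec A [block_spec()].
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A list with
#'   * `X`: samples x variables matrix with ids,
#'   * `truth`: list with `level1` and `level2` integer partitions (0 marks
#'     the planted noise variables) and `signal_fraction` per variable,
#'   * `population_correlation`: the closed-form correlation matrix implied
#'     by the spec (on the latent Gaussian scale).
#' @export
generate_hierarchical_blocks <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "block_spec"))
  n <- spec$n_samples
  rho <- spec$cross_parent_correlation
  with_seed(substream_seed(seed, "synthdata"), {
    P <- length(spec$parent_blocks)
    shared <- scale(stats::rnorm(n))[, 1L]
    parent_factors <- vapply(seq_len(P), function(p) {
      own <- scale(stats::rnorm(n))[, 1L]
      if (rho > 0) sqrt(rho) * shared + sqrt(1 - rho) * own else own
    }, numeric(n))
    cols <- list(); lev1 <- integer(); lev2 <- integer(); sf <- numeric()
    child_id <- 0L
    for (p in seq_len(P)) {
      pb <- spec$parent_blocks[[p]]
      children <- pb$children
      if (is.null(children) || !length(children))
        children <- list(list(size = pb$size, child_share = 0))
      for (ch in children) {
        child_id <- child_id + 1L
        Fc <- scale(stats::rnorm(n))[, 1L]
        for (v in seq_len(ch$size)) {
          ps <- pb$parent_share; cs <- ch$child_share
          x <- sqrt(ps) * parent_factors[, p] + sqrt(cs) * Fc +
            sqrt(1 - ps - cs) * stats::rnorm(n)
          cols[[length(cols) + 1L]] <- x
          lev1 <- c(lev1, p); lev2 <- c(lev2, child_id)
          sf <- c(sf, ps + cs)
        }
      }
    }
    for (v in seq_len(spec$n_noise_variables)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(n)
      lev1 <- c(lev1, 0L); lev2 <- c(lev2, 0L); sf <- c(sf, 0)
    }
    X <- do.call(cbind, cols)
    X <- apply_marginal(X, spec$marginal)
    colnames(X) <- sprintf("V%03d", seq_len(ncol(X)))
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
    list(X = X,
         truth = list(level1 = lev1, level2 = lev2, signal_fraction = sf),
         population_correlation = population_correlation(spec))
  })
}

# Monotone marginal transforms: rank structure of the latent Gaussian is
# preserved exactly, Pearson correlations only approximately.
apply_marginal <- function(X, marginal) {
  switch(marginal,
         normal = X,
         lognormal = exp(X),
         mixture = X + 2.5 * tanh(2 * X))
}

#' Closed-form population correlation of a planted block spec
#'
#' On the latent Gaussian scale: `ps + cs` within a child, `ps` within a
#' parent across children, `sqrt(ps_i * ps_j) * rho` across parents, 0 for
#' noise variables.
#'
#' @param spec A [block_spec()].
#' @return Correlation matrix over all variables in spec order.
#' @export
population_correlation <- function(spec) {
  ps <- numeric(); cs <- numeric(); lev1 <- integer(); lev2 <- integer()
  child_id <- 0L
  for (p in seq_along(spec$parent_blocks)) {
    pb <- spec$parent_blocks[[p]]
    children <- pb$children
    if (is.null(children) || !length(children))
      children <- list(list(size = pb$size, child_share = 0))
    for (ch in children) {
      child_id <- child_id + 1L
      ps <- c(ps, rep(pb$parent_share, ch$size))
      cs <- c(cs, rep(ch$child_share, ch$size))
      lev1 <- c(lev1, rep(p, ch$size)); lev2 <- c(lev2, rep(child_id, ch$size))
    }
  }
  nno <- spec$n_noise_variables
  ps <- c(ps, rep(0, nno)); cs <- c(cs, rep(0, nno))
  lev1 <- c(lev1, rep(0L, nno)); lev2 <- c(lev2, rep(0L, nno))
  m <- length(ps)
  R <- matrix(0, m, m)
  rho <- spec$cross_parent_correlation
  for (i in seq_len(m)) for (j in seq_len(m)) {
    R[i, j] <-
      if (i == j) 1
      else if (lev1[i] == 0L || lev1[j] == 0L) 0
      else if (lev2[i] == lev2[j]) ps[i] + cs[i]
      else if (lev1[i] == lev1[j]) ps[i]
      else sqrt(ps[i] * ps[j]) * rho
  }
  R
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert–Arabie adjusted Rand index; 1 for identical partitions
#' (up to label renaming), ~0 for independent ones.
#'
#' @param a,b Integer label vectors over the same variables.
#' @return ARI in `[-1, 1]`.
#' @export
ground_truth_ari <- function(a, b) {
  if (length(a) != length(b))
    stop_hcrsim("partitions must cover the same variables",
                "hcrsim_validation_error")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
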