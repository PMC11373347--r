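# Hierarchical cluster-wise PCA decomposition (HCD) and reconstruction.
#
# Level 1 partitions the variables with the adaptive stage (MCL + noise
# designation) and summarises each cluster by its leading k principal
# components.  Deeper levels subdivide clusters with the separator stage and
# fit k components to the *residuals*, so for every variable, at every
# level,
#     Var(X_i) = Var(X_i^R) + Var(E_i)
# holds exactly (the residual is orthogonal to all retained components of
# the variable's clusters), and the total variance explained V_E = V_XR/V_X
# is the convergence criterion.

#' Principal components of one cluster
#'
#' Centers the submatrix and returns the leading
#' `min(k, n_members, n_samples - 1)` principal components by SVD.  The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making results reproducible across linear-algebra backends.
#'
#' @param Xc Samples x members numeric matrix (one cluster).
#' @param k Maximum number of components.
#' @return A list with `scores` (n x n_pcs, mutually orthogonal, zero mean),
#'   `loadings` (n_pcs x members), `center` (per-member means),
#'   `pc_variances` (non-increasing), `n_pcs`.
#' @export
cluster_pca <- function(Xc, k) {
  check_matrix(Xc, "Xc")
  if (nrow(Xc) < 2L) stop_hcrsim("need >= 2 samples", "hcrsim_validation_error")
  if (k < 1L) stop_hcrsim("k must be >= 1", "hcrsim_validation_error")
  n <- nrow(Xc); m <- ncol(Xc)
  ctr <- colMeans(Xc)
  Z <- sweep(Xc, 2L, ctr, "-")
  if (max(abs(Z)) < 1e-300)
    stop_hcrsim("cluster submatrix is constant", "hcrsim_validation_error")
  npc <- as.integer(min(k, m, n - 1L))
  sv <- svd(Z, nu = npc, nv = npc)
  d <- sv$d[seq_len(npc)]
  scores <- sv$u * rep(d, each = n)
  loadings <- t(sv$v)
  for (p in seq_len(npc)) {           # deterministic sign convention
    jmax <- which.max(abs(loadings[p, ]))
    if (loadings[p, jmax] < 0) {
      loadings[p, ] <- -loadings[p, ]
      scores[, p] <- -scores[, p]
    }
  }
  list(scores = scores, loadings = loadings, center = ctr,
       pc_variances = d^2 / (n - 1L), n_pcs = npc)
}

#' Default settings for the adaptive and separator clustering stages
#'
#' @param similarity_threshold Squared-correlation entries below this are
#'   zeroed before Markov clustering; removes edges carrying spurious shared
#'   variance so that unstructured variables fall out as singletons (and
#'   hence into the noise subset).  Default 0.1.
#' @param inflation,max_iter,prune_threshold,conv_tol Passed to [mcl()].
#' @param min_size,rel_frac Passed to [designate_noise()].
#' @param n_range Candidate sub-cluster counts for [separator_split()],
#'   default `2:7`.
#' @return A list of settings consumed by [hcr_fit()].
#' @export
clustering_config <- function(similarity_threshold = 0.1,
                              inflation = 2, max_iter = 100L,
                              prune_threshold = 1e-5, conv_tol = 1e-8,
                              min_size = 3L, rel_frac = 0,
                              n_range = 2:7) {
  list(similarity_threshold = similarity_threshold, inflation = inflation,
       max_iter = max_iter, prune_threshold = prune_threshold,
       conv_tol = conv_tol, min_size = min_size, rel_frac = rel_frac,
       n_range = n_range)
}

# Every level-(l+1) cluster must be a subset of exactly one level-l cluster
# and the noise subset must be identical across levels.
check_nested_partitions <- function(ps) {
  if (length(ps) < 1L)
    stop_hcrsim("need at least one partition", "hcrsim_validation_error")
  for (l in seq_along(ps)[-1L]) {
    if (length(ps[[l]]) != length(ps[[1L]]))
      stop_hcrsim("partitions must cover the same variables",
                  "hcrsim_validation_error")
    if (!identical(ps[[l]] == 0L, ps[[1L]] == 0L))
      stop_hcrsim("noise subset must be identical across levels",
                  "hcrsim_validation_error")
    for (cid in unique(ps[[l]][ps[[l]] > 0L]))
      if (length(unique(ps[[l - 1L]][ps[[l]] == cid])) != 1L)
        stop_hcrsim(sprintf(
          "partitions are not nested: level-%d cluster %d spans several level-%d clusters",
          l, cid, l - 1L), "hcrsim_validation_error")
  }
  invisible(ps)
}

# The adaptive stage: sparsified squared-correlation graph -> MCL -> noise
# designation.  Returns labels over all variables, 0 = noise subset.
adaptive_partition <- function(X, cfg) {
  S <- correlation_similarity(X)
  S[S < cfg$similarity_threshold] <- 0
  diag(S) <- 1
  labels <- mcl(S, inflation = cfg$inflation, max_iter = cfg$max_iter,
                prune_threshold = cfg$prune_threshold,
                conv_tol = cfg$conv_tol)
  designate_noise(labels, min_size = cfg$min_size, rel_frac = cfg$rel_frac)
}

#' Fit the hierarchical cluster-wise PCA decomposition
#'
#' @param X Samples x variables matrix (complete, >= 2 samples).
#' @param f_E Target fraction of total variance to explain, in `(0, 1]`.
#' @param k Maximum number of principal components per (sub)cluster.
#' @param g_max Maximum number of hierarchy levels, default 3 (in practice
#'   the residual signal after two to three levels is indistinguishable from
#'   noise).
#' @param clustering Settings from [clustering_config()].
#' @param seed Integer master seed (recorded; the fit itself is
#'   deterministic).
#' @param partition Optional precomputed level-1 labels (0 = noise subset)
#'   replacing the adaptive stage.  Alternatively a *list* of label vectors,
#'   one per hierarchy level (nested partitions), replacing both the
#'   adaptive and the separator stage; the decomposition then has exactly
#'   `length(partition)` levels (capped by `f_E`).  Any external clustering
#'   can be plugged in this way.
#' @param standardize If `TRUE`, variables are scaled to unit variance
#'   before fitting (WGCNA-style usage); default `FALSE` so the variance
#'   ledger is in raw units.
#' @param full_explain_tol A cluster whose residual variance fraction falls
#'   below this is frozen: it receives no further components and is not
#'   subdivided.
#' @return An object of class `hcd_model`; see [reconstruct()],
#'   [hcs_simulate()], [variance_explained()], [pc_count_summary()].
#' @export
hcr_fit <- function(X, f_E = 0.5, k = 5L, g_max = 3L,
                    clustering = clustering_config(), seed = 1L,
                    partition = NULL, standardize = FALSE,
                    full_explain_tol = 1e-6) {
  X <- validate_expression_matrix(X)
  if (f_E <= 0 || f_E > 1)
    stop_hcrsim("f_E must be in (0, 1]", "hcrsim_validation_error")
  if (k < 1L || g_max < 1L)
    stop_hcrsim("k and g_max must be >= 1", "hcrsim_validation_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  require_nonzero_variance(X)
  if (standardize) X <- scale(X)[, , drop = FALSE]
  n <- nrow(X); nv <- ncol(X)

  fixed_partitions <- NULL
  if (is.list(partition)) {
    fixed_partitions <- lapply(partition, function(p) {
      validate_partition(p); as.integer(p)
    })
    check_nested_partitions(fixed_partitions)
    partition <- fixed_partitions[[1L]]
    g_max <- length(fixed_partitions)
  }
  labels1 <- if (is.null(partition)) adaptive_partition(X, clustering)
             else { validate_partition(partition); as.integer(partition) }
  if (length(labels1) != nv)
    stop_hcrsim("partition length does not match variable count",
                "hcrsim_validation_error")
  if (!any(labels1 > 0L))
    stop_hcrsim("no non-noise clusters at level 1", "hcrsim_validation_error")

  original_variances <- col_vars(X)
  V_X <- sum(original_variances)
  V_signal <- sum(original_variances[labels1 > 0L])
  if (f_E * V_X > V_signal + 1e-12 * V_X)
    stop(structure(
      class = c("hcrsim_insufficient_variance_error", "hcrsim_error",
                "error", "condition"),
      list(message = sprintf(
             paste0("not enough variance in the noiseless part: ",
                    "f_E * V_X = %.6g exceeds V(C != 0) = %.6g"),
             f_E * V_X, V_signal),
           call = sys.call(),
           required = f_E * V_X, available = V_signal)))

  centers <- colMeans(X)
  E <- sweep(X, 2L, centers, "-")
  labels <- labels1
  frozen <- rep(FALSE, nv)             # per-variable: cluster frozen?
  levels_out <- list()
  v_explained_trace <- numeric()

  for (lev in seq_len(g_max)) {
    cl_ids <- sort(unique(labels[labels > 0L]))
    fits <- list()
    for (cid in cl_ids) {
      members <- which(labels == cid)
      if (all(frozen[members])) next
      fit <- cluster_pca(E[, members, drop = FALSE], k)
      recon <- sweep(fit$scores %*% fit$loadings, 2L, fit$center, "+")
      E[, members] <- E[, members, drop = FALSE] - recon
      fits[[as.character(cid)]] <- c(fit, list(cluster_id = cid,
                                               level = lev,
                                               members = members))
    }
    levels_out[[lev]] <- list(labels = labels, clusters = fits)
    resid_var <- col_vars(E)
    resid_var[labels == 0L] <- original_variances[labels == 0L]
    V_E <- 1 - sum(resid_var) / V_X
    v_explained_trace[lev] <- V_E
    # freeze fully explained clusters
    for (cid in cl_ids) {
      members <- which(labels == cid)
      if (sum(resid_var[members]) <
          full_explain_tol * sum(original_variances[members]))
        frozen[members] <- TRUE
    }
    if (V_E >= f_E || lev == g_max) break
    if (!is.null(fixed_partitions)) {
      labels <- fixed_partitions[[lev + 1L]]
      next
    }
    # subdivide clusters with unexplained variance for the next level
    new_labels <- labels
    next_id <- 0L
    for (cid in cl_ids) {
      members <- which(labels == cid)
      if (all(frozen[members]) || length(members) < 2L ||
          length(members) < min(clustering$n_range)) {
        next_id <- next_id + 1L
        new_labels[members] <- next_id
      } else {
        sp <- separator_split(E[, members, drop = FALSE],
                              n_range = clustering$n_range,
                              X_orig = X[, members, drop = FALSE])
        new_labels[members] <- next_id + sp$labels
        next_id <- next_id + max(sp$labels)
      }
    }
    labels <- new_labels
  }

  resid_var <- col_vars(E)
  resid_var[labels1 == 0L] <- original_variances[labels1 == 0L]
  structure(list(
    variable_ids = colnames(X),
    sample_ids = rownames(X),
    n_samples = n,
    k = as.integer(k), f_E = f_E, g_max = as.integer(g_max),
    seed = as.integer(seed),
    standardize = standardize,
    centers = centers,
    noise_idx = which(labels1 == 0L),
    levels = levels_out,
    original_variances = original_variances,
    residual_variances = resid_var,
    v_explained = v_explained_trace[length(v_explained_trace)],
    v_explained_trace = v_explained_trace,
    clustering = clustering,
    schema_version = "1"),
    class = "hcd_model")
}

#' @export
print.hcd_model <- function(x, ...) {
  pcs <- pc_count_summary(x)
  cat(sprintf(
    paste0("Hierarchical cluster-wise PCA decomposition\n",
           "  %d variables x %d samples, %d level(s), k = %d\n",
           "  clusters per level: %s; noise subset: %d variables\n",
           "  components: %d total, at most %d per variable\n",
           "  variance explained V_E = %.4f (target f_E = %.2f)\n"),
    length(x$variable_ids), x$n_samples, length(x$levels), x$k,
    paste(vapply(x$levels, function(l) length(l$clusters), integer(1)),
          collapse = ", "),
    length(x$noise_idx), pcs$total_pcs, pcs$max_pcs_per_variable,
    x$v_explained, x$f_E))
  invisible(x)
}

#' Reconstruct the data from a fitted decomposition
#'
#' Sums each variable's retained components over the hierarchy levels and
#' adds back the variable means.  Noise-subset variables carry no component
#' signal and are returned at their mean.
#'
#' @param model A fitted `hcd_model`.
#' @param up_to_level Use only the first `up_to_level` levels; default all.
#' @return Samples x variables matrix with the model's ids.
#' @export
reconstruct <- function(model, up_to_level = NULL) {
  stopifnot(inherits(model, "hcd_model"))
  G <- length(model$levels)
  if (is.null(up_to_level)) up_to_level <- G
  if (up_to_level < 1L || up_to_level > G)
    stop_hcrsim(sprintf("up_to_level must be in 1..%d", G),
                "hcrsim_validation_error")
  n <- model$n_samples; nv <- length(model$variable_ids)
  XR <- matrix(0, n, nv, dimnames = list(model$sample_ids,
                                         model$variable_ids))
  for (lev in seq_len(up_to_level)) {
    for (fit in model$levels[[lev]]$clusters) {
      XR[, fit$members] <- XR[, fit$members, drop = FALSE] +
        sweep(fit$scores %*% fit$loadings, 2L, fit$center, "+")
    }
  }
  sweep(XR, 2L, model$centers, "+")
}

#' Add variance-matching noise
#'
#' Adds independent Gaussian noise to each column with variance equal to the
#' model's residual variance for that variable, so the expected variance of
#' the output equals the original variance (the variance ledger identity).
#' Fully explained variables (residual variance 0) are returned unchanged;
#' noise-subset variables receive their full original variance.
#'
#' @param XR Samples x variables matrix (reconstruction or simulation).
#' @param model The `hcd_model` providing the residual variances.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `XR` plus noise.
#' @export
add_variance_matching_noise <- function(XR, model, seed = 1L) {
  stopifnot(inherits(model, "hcd_model"))
  check_matrix(XR, "XR")
  rv <- pmax(model$residual_variances, 0)
  rv[rv < 1e-12] <- 0
  n <- nrow(XR)
  with_seed(substream_seed(seed, "variance_matching_noise"), {
    for (j in seq_len(ncol(XR)))
      if (rv[j] > 0) XR[, j] <- XR[, j] + stats::rnorm(n, sd = sqrt(rv[j]))
    XR
  })
}

#' Total fraction of variance explained
#'
#' `V_E = sum_i Var(X_i^R) / sum_i Var(X_i)`, computed from the variance
#' ledger identity `Var(X) = Var(X^R) + Var(E)`.
#'
#' @param model A fitted `hcd_model`.
#' @return A value in `[0, 1]`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "hcd_model"))
  1 - sum(model$residual_variances) / sum(model$original_variances)
}

#' Count the components of a decomposition
#'
#' @param model A fitted `hcd_model`.
#' @return List with `total_pcs` (sum of components over all (sub)clusters
#'   and levels) and `max_pcs_per_variable` (each variable is a linear
#'   combination of at most `g * k` components).
#' @export
pc_count_summary <- function(model) {
  stopifnot(inherits(model, "hcd_model"))
  total <- 0L
  per_var <- integer(length(model$variable_ids))
  for (lev in model$levels) {
    for (fit in lev$clusters) {
      total <- total + fit$n_pcs
      per_var[fit$members] <- per_var[fit$members] + fit$n_pcs
    }
  }
  list(total_pcs = total, max_pcs_per_variable = max(per_var))
}
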