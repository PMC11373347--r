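# The two clustering stages of the decomposition:
#  * the "adaptive" stage: Markov clustering (MCL) of the squared-Pearson
#    similarity graph, followed by designation of a noise subset C0;
#  * the "separator" stage: complete-linkage subdivision of one cluster's
#    residuals with the cut chosen by maximal normalized entropy.

#' Squared-Pearson similarity matrix
#'
#' Computes `S[i, j] = cor(X[, i], X[, j])^2`, the edge weight used both for
#' the initial Markov clustering and for the correlation-network statistics.
#'
#' @param X Samples x variables numeric matrix.
#' @param diagonal One of `"one"` or `"zero"`: value placed on the diagonal.
#' @return Symmetric matrix with entries in `[0, 1]`.
#' @export
correlation_similarity <- function(X, diagonal = c("one", "zero")) {
  diagonal <- match.arg(diagonal)
  check_matrix(X, "X")
  require_nonzero_variance(X)
  S <- stats::cor(X)^2
  # clip rounding error
  S[S > 1] <- 1
  S[S < 0] <- 0
  diag(S) <- if (diagonal == "one") 1 else 0
  S
}

#' Markov clustering of a similarity graph
#'
#' Alternates expansion (squaring of the column-stochastic transition
#' matrix) and inflation (elementwise power followed by column
#' re-normalization), pruning entries below `prune_threshold`, until the
#' iterate changes by less than `conv_tol` or `max_iter` is reached.
#' Clusters are read off the converged matrix as attractor-based weakly
#' connected components; nodes supported by no attractor become singletons.
#'
#' @param S Symmetric non-negative similarity matrix.
#' @param inflation Inflation exponent (> 1), default 2.
#' @param max_iter Maximum number of expansion/inflation rounds.
#' @param prune_threshold Entries below this are zeroed before
#'   re-normalization.
#' @param conv_tol Convergence tolerance on the max absolute change.
#' @param add_self_loops If `TRUE` (default) the diagonal is set to the
#'   maximal off-diagonal entry of each column before normalization, the
#'   usual regularisation of the MCL literature.
#' @return Integer vector of cluster labels `1..n_clusters` (no noise label
#'   at this stage; see [designate_noise()]).
#' @export
mcl <- function(S, inflation = 2, max_iter = 100L,
                prune_threshold = 1e-5, conv_tol = 1e-8,
                add_self_loops = TRUE) {
  check_matrix(S, "S")
  n <- nrow(S)
  if (ncol(S) != n) stop_hcrsim("S must be square", "hcrsim_validation_error")
  if (max(abs(S - t(S))) > 1e-8)
    stop_hcrsim("S must be symmetric", "hcrsim_validation_error")
  if (min(S) < 0)
    stop_hcrsim("S must be non-negative", "hcrsim_validation_error")
  if (inflation <= 1) stop_hcrsim("inflation must be > 1",
                                  "hcrsim_validation_error")
  M <- S
  if (add_self_loops) {
    offdiag_max <- apply(`diag<-`(M, 0), 2L, max)
    diag(M) <- ifelse(offdiag_max > 0, offdiag_max, 1)
  }
  normalize_cols <- function(M) {
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) {            # isolated node: make it absorbing
      M[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    sweep(M, 2L, cs, "/")
  }
  M <- normalize_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2[M2 < prune_threshold] <- 0
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < conv_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; reading clusters off the last iterate")
  read_mcl_clusters(M, eps = prune_threshold)
}

# Interpret a converged MCL matrix.  Attractors are rows with non-negligible
# converged diagonal mass; attractors sharing a column's support form one
# attractor system; every column is assigned to the system of the
# lowest-index attractor in its support.
read_mcl_clusters <- function(M, eps = 1e-5) {
  n <- nrow(M)
  attractors <- which(diag(M) > eps)
  labels <- integer(n)
  if (length(attractors)) {
    supp <- M[attractors, , drop = FALSE] > eps
    # connect attractors co-occurring in at least one column
    co <- (supp %*% t(supp)) > 0
    g <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                             diag = FALSE)
    sys_id <- igraph::components(g)$membership
    for (j in seq_len(n)) {
      hit <- which(supp[, j])
      if (length(hit)) labels[j] <- sys_id[min(hit)]
    }
  }
  # nodes in no attractor's basin: singleton clusters
  orphan <- labels == 0L
  if (any(orphan))
    labels[orphan] <- max(labels) + seq_len(sum(orphan))
  # renumber contiguously in order of first appearance
  as.integer(factor(labels, levels = unique(labels)))
}

#' Designate small clusters as the noise subset
#'
#' Clusters significantly smaller than the rest carry no usable correlation
#' structure; they are relabelled 0 (the noise subset C0) and excluded from
#' component modelling.  A cluster is noise when its size is below
#' `max(min_size, rel_frac * median non-singleton cluster size)`.  Remaining
#' clusters are renumbered `1..n` by decreasing size.
#'
#' @param labels Integer cluster labels (from [mcl()] or any partitioner).
#' @param min_size Absolute size threshold, default 3.
#' @param rel_frac Relative threshold against the median non-singleton
#'   cluster size; 0 (default) disables the relative rule.
#' @return Integer labels with 0 marking the noise subset.
#' @export
designate_noise <- function(labels, min_size = 3L, rel_frac = 0) {
  labels <- as.integer(labels)
  if (!length(labels) || all(labels == 0L))
    stop_hcrsim("partition has no clusters", "hcrsim_validation_error")
  sizes <- table(labels[labels != 0L])
  nonsing <- as.integer(sizes[sizes > 1L])
  med <- if (length(nonsing)) stats::median(nonsing) else 0
  threshold <- max(min_size, rel_frac * med)
  noise_ids <- as.integer(names(sizes)[as.integer(sizes) < threshold])
  out <- labels
  out[out %in% noise_ids] <- 0L
  keep <- table(out[out != 0L])
  if (!length(keep))
    stop_hcrsim(paste0("all clusters fall below the noise threshold (",
                       format(threshold),
                       "); lower min_size or rel_frac"),
                "hcrsim_all_noise_error")
  # renumber 1..n by decreasing size, ties by old label for determinism
  ord <- order(-as.integer(keep), as.integer(names(keep)))
  remap <- integer(max(as.integer(names(keep))))
  remap[as.integer(names(keep))[ord]] <- seq_along(ord)
  out[out != 0L] <- remap[out[out != 0L]]
  out
}

#' Normalized entropy of a division
#'
#' For sub-cluster sizes `s_1..s_ng` with proportions `p_i`, returns
#' `(-sum p_i log p_i) / log(n_g)`, which is 1 exactly for an even split.
#' Used to score candidate cuts of the separator stage: it counteracts the
#' tendency of agglomerative algorithms to shave off tiny peripheral
#' sub-clusters.
#'
#' @param sizes Vector of positive sub-cluster sizes, length >= 2.
#' @return A value in `[0, 1]`.
#' @export
normalized_entropy <- function(sizes) {
  if (length(sizes) < 2L)
    stop_hcrsim("a division needs at least 2 sub-clusters",
                "hcrsim_validation_error")
  if (any(sizes <= 0))
    stop_hcrsim("sub-cluster sizes must be positive",
                "hcrsim_validation_error")
  p <- sizes / sum(sizes)
  -sum(p * log(p)) / log(length(sizes))
}

#' Separator subdivision of one cluster
#'
#' Builds a complete-linkage dendrogram on the residual distance
#' `d_ij = 1 - cor(E_i, E_j)^2`, cuts it into `n_g` sub-clusters for every
#' `n_g` in `n_range`, and keeps the cut maximizing the normalized entropy
#' (ties broken towards the smallest `n_g`).  Always yields a complete
#' partition of the cluster (no noise label).
#'
#' Because the normalized entropy saturates near 1 for every nearly even
#' candidate, cuts scoring within `tie_tol` of the maximum are treated as
#' tied and the finest of them is kept: a coarser near-even cut leaves
#' several latent factors in one sub-cluster, which the per-cluster
#' component budget then cannot explain.
#'
#' @param E Samples x members residual matrix for one cluster.
#' @param n_range Candidate numbers of sub-clusters, default `2:7`.
#' @param X_orig Optional samples x members matrix of the original data,
#'   used to place members whose residuals are numerically constant (they
#'   join the sub-cluster of their most-correlated peer).
#' @param var_tol Residual variance below this is treated as constant.
#' @param tie_tol Entropy margin within which candidate cuts count as tied.
#' @return List with `labels` (integer, 1..n_g per member), `n_g`,
#'   `entropy`, and `degenerate` (`TRUE` when no informative cut existed).
#' @export
separator_split <- function(E, n_range = 2:7, X_orig = NULL,
                            var_tol = 1e-12, tie_tol = 0.005) {
  check_matrix(E, "E")
  m <- ncol(E)
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 2L))
    stop_hcrsim("n_range values must be >= 2", "hcrsim_validation_error")
  trivial <- list(labels = rep(1L, m), n_g = 1L, entropy = NA_real_,
                  degenerate = TRUE)
  if (m < min(n_range)) return(trivial)
  v <- col_vars(E)
  ok <- which(v > var_tol)
  if (length(ok) < 2L) return(trivial)
  C2 <- stats::cor(E[, ok, drop = FALSE])^2
  d <- 1 - C2
  d[d < 0] <- 0
  if (max(d) < 1e-12) {
    # all residuals mutually perfectly correlated: no informative cut;
    # fall back to the coarsest even split by member order
    ng <- min(n_range)
    labels_ok <- as.integer(cut(seq_along(ok), breaks = ng, labels = FALSE))
    labels <- assign_excluded(labels_ok, ok, m, E, X_orig)
    return(list(labels = labels, n_g = ng, entropy = 1,
                degenerate = TRUE))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cand <- list()
  for (ng in n_range) {
    if (ng > length(ok)) break
    cut_labels <- stats::cutree(hc, k = ng)
    H <- normalized_entropy(tabulate(cut_labels, nbins = ng))
    cand[[length(cand) + 1L]] <-
      list(labels_ok = as.integer(cut_labels), n_g = ng, entropy = H)
  }
  H_all <- vapply(cand, `[[`, numeric(1), "entropy")
  tied <- which(H_all >= max(H_all) - tie_tol)
  best <- cand[[tied[length(tied)]]]   # finest cut among the tied ones
  labels <- assign_excluded(best$labels_ok, ok, m, E, X_orig)
  list(labels = labels, n_g = best$n_g, entropy = best$entropy,
       degenerate = FALSE)
}

# Place members excluded from the distance computation (constant residuals)
# into the sub-cluster of their most-correlated peer in the original data.
assign_excluded <- function(labels_ok, ok, m, E, X_orig) {
  labels <- integer(m)
  labels[ok] <- labels_ok
  excl <- setdiff(seq_len(m), ok)
  if (!length(excl)) return(labels)
  ref <- if (!is.null(X_orig)) X_orig else E
  for (j in excl) {
    r2 <- suppressWarnings(stats::cor(ref[, j], ref[, ok, drop = FALSE]))^2
    r2[is.na(r2)] <- -1
    labels[j] <- labels_ok[which.max(r2)]
  }
  labels
}
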