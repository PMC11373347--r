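# Weighted correlation-network statistics used to compare reference,
# reconstructed and simulated data: squared-correlation adjacency, weighted
# degree, weighted clustering coefficient (Zhang-Horvath form), topological
# overlap, dendrograms, and the cross-dataset summary metrics.

#' Weighted network adjacency
#'
#' `a_ij = cor(X_i, X_j)^2` with zero diagonal (unsigned network, no extra
#' soft-threshold power).  Computed blockwise so that datasets with ~1e4
#' variables do not require more than one n x block slab at a time.
#'
#' @param X Samples x variables matrix without zero-variance columns.
#' @param block_size Number of columns per block, default 2000.
#' @return Symmetric matrix with entries in `[0, 1]` and zero diagonal.
#' @export
adjacency <- function(X, block_size = 2000L) {
  check_matrix(X, "X")
  require_nonzero_variance(X)
  nv <- ncol(X)
  Z <- scale(X)
  A <- matrix(0, nv, nv, dimnames = list(colnames(X), colnames(X)))
  starts <- seq(1L, nv, by = block_size)
  n1 <- nrow(X) - 1L
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, nv)
    A[, idx] <- (crossprod(Z, Z[, idx, drop = FALSE]) / n1)^2
  }
  A[A > 1] <- 1
  diag(A) <- 0
  A
}

#' Weighted degree (connectivity)
#'
#' `k_i = sum_{j != i} a_ij`.
#'
#' @param A Adjacency matrix from [adjacency()].
#' @return Numeric vector of per-node degrees.
#' @export
weighted_degree <- function(A) {
  check_matrix(A, "A")
  rowSums(A) - diag(A)
}

#' Weighted clustering coefficient
#'
#' The Zhang-Horvath weighted triangle density:
#' `cc_i = sum_{j,l != i} a_ij a_jl a_li / ((sum_j a_ij)^2 - sum_j a_ij^2)`,
#' defined as 0 where the denominator vanishes.  Values lie in `[0, 1]`
#' whenever all weights do.
#'
#' @param A Adjacency matrix with zero diagonal and entries in `[0, 1]`.
#' @return Numeric vector of per-node clustering coefficients.
#' @export
clustering_coefficient <- function(A) {
  check_matrix(A, "A")
  A <- `diag<-`(A, 0)
  num <- diag(A %*% A %*% A)          # 2 x triangle weight around i
  k <- rowSums(A)
  den <- k^2 - rowSums(A^2)
  cc <- ifelse(den > 0, num / den, 0)
  cc[cc < 0] <- 0
  cc
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with unit diagonal.
#'
#' @param A Adjacency matrix with zero diagonal.
#' @return Symmetric matrix with unit diagonal.
#' @export
tom <- function(A) {
  check_matrix(A, "A")
  A <- `diag<-`(A, 0)
  L <- A %*% A                         # sum_u a_iu a_uj (diagonal unused)
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  T <- (L + A) / (kmin + 1 - A)
  diag(T) <- 1
  T
}

#' Dendrogram of a dissimilarity matrix
#'
#' Standard agglomerative clustering of `1 - TOM` (or any dissimilarity),
#' average linkage by default, as used to display the module structure of a
#' correlation network.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param linkage Agglomeration method, default `"average"`.
#' @return An `hclust` merge tree.
#' @export
network_dendrogram <- function(D, linkage = "average") {
  check_matrix(D, "D")
  if (nrow(D) != ncol(D))
    stop_hcrsim("dissimilarity matrix must be square",
                "hcrsim_validation_error")
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` tree.
#' @param path Output file path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Compare the correlation structure of two datasets
#'
#' Computes the three cross-dataset summary metrics: the maximal and the
#' average squared Pearson correlation over all cross pairs
#' `(X_ref_i, X_query_j)` and the RMSE between the two correlation matrices
#' over unordered off-diagonal pairs.  For a reconstruction, large `r_max`
#' and small `cr_rmse` indicate fidelity; for a simulation, `r_max`/`r_avg`
#' should be at the noise level while `cr_rmse` stays small.
#'
#' @param X_ref,X_query Samples x variables matrices with the same variable
#'   count and order (sample counts may differ).
#' @return List with `r_max`, `r_avg`, `cr_rmse`.
#' @export
compare_structures <- function(X_ref, X_query) {
  check_matrix(X_ref, "X_ref"); check_matrix(X_query, "X_query")
  if (ncol(X_ref) != ncol(X_query))
    stop_hcrsim("variable counts differ", "hcrsim_validation_error")
  require_nonzero_variance(X_ref); require_nonzero_variance(X_query)
  if (nrow(X_ref) == nrow(X_query)) {
    cross <- stats::cor(X_ref, X_query)^2
    r_max <- max(cross); r_avg <- mean(cross)
  } else {
    r_max <- NA_real_; r_avg <- NA_real_   # cross-correlation needs paired samples
  }
  cref <- stats::cor(X_ref); cq <- stats::cor(X_query)
  ut <- upper.tri(cref)
  cr_rmse <- sqrt(mean((cref[ut] - cq[ut])^2))
  list(r_max = r_max, r_avg = r_avg, cr_rmse = cr_rmse)
}

#' Topology distribution summary of a dataset
#'
#' Convenience wrapper returning per-variable weighted degree and clustering
#' coefficient (the two distributions used to judge whether synthetic data
#' reproduces the reference network topology), plus the two-sample
#' Kolmogorov-Smirnov statistic against a reference dataset when given.
#'
#' @param X Samples x variables matrix.
#' @param X_ref Optional reference matrix for the KS comparison.
#' @return data.frame (variable_id, degree, cc); if `X_ref` is supplied,
#'   attributes `ks_degree` and `ks_cc` hold the KS statistics.
#' @export
topology_summary <- function(X, X_ref = NULL) {
  A <- adjacency(X)
  out <- data.frame(variable_id = colnames(X),
                    degree = weighted_degree(A),
                    cc = clustering_coefficient(A))
  if (!is.null(X_ref)) {
    Ar <- adjacency(X_ref)
    attr(out, "ks_degree") <- unname(suppressWarnings(
      stats::ks.test(out$degree, weighted_degree(Ar))$statistic))
    attr(out, "ks_cc") <- unname(suppressWarnings(
      stats::ks.test(out$cc, clustering_coefficient(Ar))$statistic))
  }
  out
}
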