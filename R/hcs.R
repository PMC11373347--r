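# Simulation of new datasets from a fitted decomposition.
#
# The correlation matrix of all retained components is estimated from their
# score vectors, repaired to positive definite if needed, and used to draw
# synthetic component scores that are independent of the original samples
# but correlated like the original components.  Each simulated variable is
# the same linear combination of components as in the reconstruction, plus
# variance-matching noise.  Two variants: normal component marginals
# ("normal") or metalog-fitted marginals coupled through a Gaussian copula
# ("fitted").

#' Correlation model of the retained components
#'
#' Assembles all retained component score vectors, computes their Pearson
#' correlation matrix, repairs it to positive definite by flooring
#' eigenvalues at `eig_floor` and rescaling to unit diagonal, and stores a
#' lower-triangular factor of the repaired matrix.
#'
#' @param model A fitted `hcd_model`.
#' @param eig_floor Eigenvalue floor for the repair, default 1e-10.
#' @return An object of class `pc_correlation_model` with `pc_ids`
#'   (data.frame: level, cluster, pc), `correlation`, `factor`
#'   (`factor %*% t(factor)` reproduces the repaired matrix), `pc_sds`
#'   (score standard deviations), `repair_log`.
#' @export
pc_correlation_model <- function(model, eig_floor = 1e-10) {
  stopifnot(inherits(model, "hcd_model"))
  scores <- list(); ids <- list()
  for (lev_i in seq_along(model$levels)) {
    for (fit in model$levels[[lev_i]]$clusters) {
      for (p in seq_len(fit$n_pcs)) {
        scores[[length(scores) + 1L]] <- fit$scores[, p]
        ids[[length(ids) + 1L]] <-
          data.frame(level = lev_i, cluster = fit$cluster_id, pc = p)
      }
    }
  }
  if (!length(scores))
    stop_hcrsim("model has no components", "hcrsim_validation_error")
  S <- do.call(cbind, scores)
  M <- ncol(S)
  if (M > model$n_samples - 1L)
    warning("more components (", M, ") than samples - 1 (",
            model$n_samples - 1L, "): correlation matrix is rank ",
            "deficient and will be repaired")
  R <- stats::cor(S)
  eig <- eigen(R, symmetric = TRUE)
  repair <- NULL
  if (min(eig$values) < eig_floor) {
    vals <- pmax(eig$values, eig_floor)
    R2 <- eig$vectors %*% (vals * t(eig$vectors))
    R2 <- stats::cov2cor(R2)
    repair <- list(eig_floor = eig_floor,
                   min_eigenvalue_before = min(eig$values),
                   frobenius_change = sqrt(sum((R2 - R)^2)))
    R <- R2
    eig <- eigen(R, symmetric = TRUE)
  }
  # lower-triangular-like factor via eigendecomposition (robust to the
  # near-singular case); chol when comfortably PD
  L <- if (min(eig$values) > 1e-8) t(chol(R))
       else eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), M)
  structure(list(pc_ids = do.call(rbind, ids),
                 correlation = R, factor = L,
                 pc_sds = apply(S, 2L, stats::sd),
                 scores = S,
                 repair_log = repair),
            class = "pc_correlation_model")
}

#' Draw synthetic component scores
#'
#' Draws standard normal vectors, couples them through the factor of the
#' repaired component correlation matrix and either rescales each column to
#' the source component's variance (`variant = "normal"`) or maps it through
#' the standard normal CDF and the component's metalog quantile function
#' (`variant = "fitted"`, a Gaussian-copula coupling; an infeasible fit
#' falls back to the normal marginal).
#'
#' @param pcm A [pc_correlation_model()].
#' @param variant `"normal"` or `"fitted"`.
#' @param fits List of `metalog_fit` objects, one per component (fitted
#'   variant only).
#' @param n Number of samples to draw.
#' @param seed Integer seed.
#' @return `n` x M matrix of synthetic scores, columns ordered as
#'   `pcm$pc_ids`.
#' @export
simulate_pcs <- function(pcm, variant = c("normal", "fitted"), fits = NULL,
                         n = 100L, seed = 1L) {
  stopifnot(inherits(pcm, "pc_correlation_model"))
  variant <- match.arg(variant)
  M <- ncol(pcm$correlation)
  if (variant == "fitted") {
    if (is.null(fits) || length(fits) != M)
      stop_hcrsim("variant = \"fitted\" needs one metalog fit per component",
                  "hcrsim_validation_error")
  }
  Z <- with_seed(substream_seed(seed, "simulate_pcs"),
                 matrix(stats::rnorm(n * M), n, M))
  Y <- Z %*% t(pcm$factor)            # rows have correlation ~ repaired R
  if (variant == "normal") {
    Y <- sweep(Y, 2L, pcm$pc_sds, "*")
  } else {
    U <- stats::pnorm(Y)
    U <- pmin(pmax(U, 1e-9), 1 - 1e-9)
    for (m in seq_len(M)) {
      f <- fits[[m]]
      Y[, m] <- if (inherits(f, "metalog_fit") && f$feasible)
        metalog_quantile(f, U[, m])
      else stats::qnorm(U[, m], sd = pcm$pc_sds[m])
    }
  }
  Y
}

#' Simulate a new dataset from a fitted decomposition
#'
#' Replaces the original component scores with synthetic ones drawn from the
#' component correlation model, recombines them through the fitted loadings,
#' and (by default) adds variance-matching noise so each simulated variable
#' has the variance of its real counterpart.  No original sample data enters
#' the draw, so the simulated samples are independent of the reference ones.
#' Noise-subset variables carry no component signal: they are returned at
#' their mean, plus full-variance noise when `add_noise = TRUE`.
#'
#' @param model A fitted `hcd_model`.
#' @param variant `"normal"` (normal component marginals) or `"fitted"`
#'   (metalog marginals via Gaussian copula).
#' @param n Number of samples to simulate; defaults to the source size.
#' @param seed Integer master seed.
#' @param add_noise Add the variance-matching noise step (recommended;
#'   without it the simulated network topology is visibly too clean).
#' @param n_terms Metalog term count for the fitted variant.
#' @return A list of class `hcs_simulation`: `values` (n x variables),
#'   `variant`, `noise_added`, `seed`, plus `metalog_fits` for the fitted
#'   variant.
#' @export
hcs_simulate <- function(model, variant = c("normal", "fitted"),
                         n = NULL, seed = 1L, add_noise = TRUE,
                         n_terms = 5L) {
  stopifnot(inherits(model, "hcd_model"))
  variant <- match.arg(variant)
  if (is.null(n)) n <- model$n_samples
  if (n < 2L) stop_hcrsim("n must be >= 2", "hcrsim_validation_error")
  pcm <- pc_correlation_model(model)
  fits <- NULL
  if (variant == "fitted")
    fits <- lapply(seq_len(ncol(pcm$scores)),
                   function(m) metalog_fit(pcm$scores[, m], n_terms))
  P <- simulate_pcs(pcm, variant, fits, n = n, seed = seed)
  nv <- length(model$variable_ids)
  XS <- matrix(0, n, nv,
               dimnames = list(sprintf("sim%04d", seq_len(n)),
                               model$variable_ids))
  col_of <- seq_len(nrow(pcm$pc_ids))
  for (lev_i in seq_along(model$levels)) {
    for (fit in model$levels[[lev_i]]$clusters) {
      sel <- which(pcm$pc_ids$level == lev_i &
                   pcm$pc_ids$cluster == fit$cluster_id)
      XS[, fit$members] <- XS[, fit$members, drop = FALSE] +
        sweep(P[, sel, drop = FALSE] %*% fit$loadings, 2L, fit$center, "+")
    }
  }
  XS <- sweep(XS, 2L, model$centers, "+")
  if (add_noise)
    XS <- add_variance_matching_noise(XS, model,
                                      seed = substream_seed(seed, "hcs_noise"))
  structure(list(values = XS, variant = variant, noise_added = add_noise,
                 seed = as.integer(seed), n = as.integer(n),
                 metalog_fits = fits),
            class = "hcs_simulation")
}

#' @export
print.hcs_simulation <- function(x, ...) {
  cat(sprintf("HCS(%s) simulation: %d samples x %d variables%s, seed %d\n",
              substr(x$variant, 1, 1), nrow(x$values), ncol(x$values),
              if (x$noise_added) " (+noise)" else "", x$seed))
  invisible(x)
}
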