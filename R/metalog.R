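# Metalog quantile-parameterized distributions (unbounded form).
#
# The metalog family has a closed-form quantile function
#   M(y) = a1 + a2*L + a3*(y - 1/2)*L + a4*(y - 1/2) + a5*(y - 1/2)^2 + ...
# with L = ln(y / (1 - y)), is fit by ordinary least squares of empirical
# quantiles on the basis terms, and can represent multimodal shapes.  The
# 2-term metalog is exactly the logistic distribution with location a1 and
# scale a2.  Used to model the marginal distributions of the latent
# components in the fitted-marginal simulation variant.

# Basis matrix of the unbounded metalog at probabilities y.
metalog_basis <- function(y, n_terms) {
  L <- log(y / (1 - y))
  ym <- y - 0.5
  B <- matrix(0, length(y), n_terms)
  B[, 1L] <- 1
  if (n_terms >= 2L) B[, 2L] <- L
  if (n_terms >= 3L) B[, 3L] <- ym * L
  if (n_terms >= 4L) B[, 4L] <- ym
  j <- 5L
  pw <- 2L
  while (j <= n_terms) {
    B[, j] <- ym^pw                      # odd extra terms: powers
    if (j + 1L <= n_terms) B[, j + 1L] <- ym^pw * L
    j <- j + 2L
    pw <- pw + 1L
  }
  B
}

#' Fit a metalog distribution to a sample
#'
#' Coefficients are obtained by least squares of the sorted sample against
#' the metalog basis at plotting positions `(i - 0.5)/n`.  Feasibility (a
#' strictly increasing quantile function) is checked on a 999-point grid
#' `y = 0.001, ..., 0.999`; on failure the term count is stepped down to 2,
#' and a still-infeasible 2-term fit is returned flagged infeasible.
#'
#' @param x Numeric sample with at least `n_terms + 2` distinct values.
#' @param n_terms Number of basis terms, default 5.
#' @return An object of class `metalog_fit` with elements `coefficients`,
#'   `n_terms`, `feasible`, `fit_residual` (sum of squared quantile errors).
#' @export
metalog_fit <- function(x, n_terms = 5L) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_hcrsim("sample contains NA", "hcrsim_validation_error")
  if (length(unique(x)) < 2L)
    stop_hcrsim("cannot fit a metalog to a constant sample",
                "hcrsim_validation_error")
  n_terms <- as.integer(n_terms)
  if (n_terms < 2L) stop_hcrsim("n_terms must be >= 2",
                                "hcrsim_validation_error")
  if (length(unique(x)) < n_terms + 2L)
    n_terms <- max(2L, length(unique(x)) - 2L)
  xs <- sort(x)
  n <- length(xs)
  y <- (seq_len(n) - 0.5) / n
  grid <- seq(0.001, 0.999, by = 0.001)
  for (m in seq(n_terms, 2L)) {
    B <- metalog_basis(y, m)
    qr_fit <- qr(B)
    a <- qr.coef(qr_fit, xs)
    if (anyNA(a)) next
    resid <- xs - B %*% a
    q <- metalog_basis(grid, m) %*% a
    if (all(diff(q) > 0)) {
      return(structure(list(coefficients = as.numeric(a), n_terms = m,
                            feasible = TRUE,
                            fit_residual = sum(resid^2)),
                       class = "metalog_fit"))
    }
    if (m == 2L)
      return(structure(list(coefficients = as.numeric(a), n_terms = 2L,
                            feasible = FALSE,
                            fit_residual = sum(resid^2)),
                       class = "metalog_fit"))
  }
  stop_hcrsim("metalog fit failed at every term count",
              "hcrsim_metalog_error")  # unreachable in practice
}

#' Metalog quantile function
#'
#' @param fit A `metalog_fit`.
#' @param y Probabilities strictly inside (0, 1).
#' @return Quantiles `M(y)`.
#' @export
metalog_quantile <- function(fit, y) {
  stopifnot(inherits(fit, "metalog_fit"))
  if (any(y <= 0 | y >= 1))
    stop_hcrsim("y must be strictly inside (0, 1)", "hcrsim_domain_error")
  as.numeric(metalog_basis(y, fit$n_terms) %*% fit$coefficients)
}

#' Sample from a fitted metalog by inverse transform
#'
#' @param fit A feasible `metalog_fit`.
#' @param n Number of draws.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return Numeric vector of length `n`.
#' @export
metalog_sample <- function(fit, n, seed = 1L) {
  stopifnot(inherits(fit, "metalog_fit"))
  if (!fit$feasible)
    stop_hcrsim(paste0("fit is infeasible (non-monotone quantile function); ",
                       "use a normal fallback for this component"),
                "hcrsim_metalog_error")
  with_seed(substream_seed(seed, "metalog_sample"), {
    u <- stats::runif(n)
    u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
    metalog_quantile(fit, u)
  })
}
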