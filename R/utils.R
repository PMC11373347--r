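# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomised stages of the pipeline draw their seed from one user seed
#' plus the stage name, so each stage is independently reproducible and
#' re-running a single stage does not perturb the others.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. `"simulate_pcs"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  b <- utf8ToInt(stage)
  h <- sum(as.double(b) * (seq_along(b) %% 31 + 1) * 1009)
  as.integer((abs(as.double(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Column variances of a numeric matrix (denominator n - 1).
col_vars <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  colSums(sweep(x, 2L, ctr, "-")^2) / (n - 1)
}

# Abort helpers -------------------------------------------------------------

stop_hcrsim <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hcrsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_matrix <- function(x, what = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_hcrsim(sprintf("`%s` must be a numeric matrix", what),
                "hcrsim_validation_error")
  if (anyNA(x))
    stop_hcrsim(sprintf("`%s` contains missing values", what),
                "hcrsim_validation_error")
  invisible(x)
}

# Indices of zero-variance columns (tolerance on the variance itself).
zero_variance_cols <- function(x, tol = 1e-12) {
  which(col_vars(x) < tol)
}

require_nonzero_variance <- function(x, tol = 1e-12) {
  zv <- zero_variance_cols(x, tol)
  if (length(zv)) {
    ids <- colnames(x)[zv]
    if (is.null(ids)) ids <- as.character(zv)
    stop_hcrsim(
      paste0("zero-variance variables: ",
             paste(utils::head(ids, 10L), collapse = ", "),
             if (length(ids) > 10L) sprintf(" (and %d more)", length(ids) - 10L)),
      "hcrsim_zero_variance_error")
  }
  invisible(x)
}
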