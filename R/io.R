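# Reading and writing expression matrices and partitions.
#
# The internal canonical orientation is samples x variables; on disk the
# default is variables in rows (genes-as-rows, the common omics convention).

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV numeric matrix with one id row (header) and one id column,
#' and returns it in the canonical samples x variables orientation with
#' sample ids as rownames and variable ids as colnames.
#'
#' @param path Path to the delimited text file.
#' @param orientation Either `"variables_in_rows"` (default; genes as rows,
#'   samples as columns) or `"samples_in_rows"`.
#' @param delimiter Field delimiter, default tab.
#' @param impute_mean If `TRUE`, missing cells are replaced by the variable
#'   mean; by default missing values are an error (the decomposition assumes
#'   complete data).
#' @return A numeric matrix, samples x variables, with dimnames.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("variables_in_rows",
                                                   "samples_in_rows"),
                                   delimiter = "\t",
                                   impute_mean = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop_hcrsim(sprintf("file not found: %s", path), "hcrsim_io_error")
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L)
    stop_hcrsim("expected an id column plus at least one data column",
                "hcrsim_validation_error")
  row_ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    # locate the first offending cell for the error message
    cn <- colnames(vals)[bad[1L]]
    col <- suppressWarnings(as.numeric(vals[[bad[1L]]]))
    rr <- which(is.na(col) & !is.na(vals[[bad[1L]]]))[1L]
    stop_hcrsim(sprintf("non-numeric value in column '%s', row '%s'",
                        cn, row_ids[rr]), "hcrsim_parse_error")
  }
  m <- as.matrix(vals)
  rownames(m) <- row_ids
  if (orientation == "variables_in_rows") m <- t(m)
  if (anyNA(m)) {
    if (impute_mean) {
      for (j in seq_len(ncol(m))) {
        nas <- is.na(m[, j])
        if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
      }
    } else {
      stop_hcrsim("matrix contains missing values (use impute_mean = TRUE to impute)",
                  "hcrsim_validation_error")
    }
  }
  validate_expression_matrix(m)
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: numeric, complete,
#' at least 2 samples, unique variable ids.
#'
#' @param x Samples x variables numeric matrix.
#' @return `x`, invisibly on success.
#' @export
validate_expression_matrix <- function(x) {
  check_matrix(x, "expression matrix")
  if (nrow(x) < 2L)
    stop_hcrsim("need at least 2 samples", "hcrsim_validation_error")
  vid <- colnames(x)
  if (!is.null(vid) && anyDuplicated(vid))
    stop_hcrsim(paste0("duplicate variable ids: ",
                       paste(unique(vid[duplicated(vid)]), collapse = ", ")),
                "hcrsim_validation_error")
  x
}

#' Write an expression matrix to delimited text
#'
#' @inheritParams read_expression_matrix
#' @param x Samples x variables numeric matrix with dimnames.
#' @param id_header Name put in the top-left header cell.
#' @export
write_expression_matrix <- function(x, path,
                                    orientation = c("variables_in_rows",
                                                    "samples_in_rows"),
                                    delimiter = "\t",
                                    id_header = "id") {
  orientation <- match.arg(orientation)
  check_matrix(x, "x")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  out <- if (orientation == "variables_in_rows") t(x) else x
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  colnames(df)[1L] <- id_header
  data.table::fwrite(df, path, sep = delimiter)
  invisible(path)
}

#' Read / write a variable partition
#'
#' Partitions are stored as two-column TSV: `variable_id`, `cluster` with
#' label 0 reserved for the noise subset.
#'
#' @param path File path.
#' @return Named integer vector of cluster labels.
#' @export
read_partition <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  labels <- as.integer(dt[[2L]])
  names(labels) <- as.character(dt[[1L]])
  validate_partition(labels)
  labels
}

#' @rdname read_partition
#' @param labels Named integer vector (0 = noise subset).
#' @export
write_partition <- function(labels, path) {
  validate_partition(labels)
  df <- data.frame(variable_id = names(labels), cluster = as.integer(labels))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

validate_partition <- function(labels) {
  if (anyNA(labels) || any(labels < 0L))
    stop_hcrsim("partition labels must be non-negative integers (0 = noise)",
                "hcrsim_validation_error")
  pos <- sort(unique(labels[labels > 0L]))
  if (length(pos) && !identical(pos, seq_along(pos)))
    stop_hcrsim("non-noise cluster labels must be contiguous 1..n",
                "hcrsim_validation_error")
  invisible(labels)
}
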