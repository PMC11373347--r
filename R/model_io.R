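# Serialization of fitted decompositions.
#
# A model archive is a single JSON document: a small metadata header
# (schema version, package version, integrity checksum) plus the full model
# payload serialized with jsonlite::serializeJSON at full precision, so a
# round trip preserves strings and integers exactly and reals to better
# than 1e-12.  The container is plain text and language-portable.

MODEL_SCHEMA_VERSION <- "1"

# Cheap order-sensitive checksum of a character payload (integrity, not
# cryptography): detects truncation and byte flips.
payload_checksum <- function(txt) {
  b <- utf8ToInt(txt)
  w <- (seq_along(b) - 1L) %% 97L + 1L
  sprintf("%d-%.0f", length(b), sum(as.double(b) * w) %% 2147483647)
}

#' Write a fitted decomposition to disk
#'
#' @param model A `hcd_model`.
#' @param path Output path (conventionally `.hcd.json`).
#' @export
write_hcd_model <- function(model, path) {
  stopifnot(inherits(model, "hcd_model"))
  payload <- as.character(jsonlite::serializeJSON(unclass(model),
                                                  digits = NA))
  doc <- list(format = "hcd-model",
              schema_version = MODEL_SCHEMA_VERSION,
              package_version = as.character(utils::packageVersion("hcrsim")),
              checksum = payload_checksum(payload),
              payload = payload)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a fitted decomposition from disk
#'
#' Fails with an explicit error on a schema version mismatch or when the
#' payload checksum does not match (truncated or corrupted file).
#'
#' @param path Path written by [write_hcd_model()].
#' @return A `hcd_model`.
#' @export
read_hcd_model <- function(path) {
  if (!file.exists(path))
    stop_hcrsim(sprintf("file not found: %s", path), "hcrsim_io_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_hcrsim(paste0("not a readable model archive: ",
                                       conditionMessage(e)),
                                "hcrsim_integrity_error"))
  if (!identical(doc$format, "hcd-model"))
    stop_hcrsim("not an hcd-model archive", "hcrsim_integrity_error")
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION))
    stop_hcrsim(sprintf(
      "schema version mismatch: archive has '%s', this package reads '%s'",
      doc$schema_version, MODEL_SCHEMA_VERSION),
      "hcrsim_version_error")
  if (!identical(payload_checksum(doc$payload), doc$checksum))
    stop_hcrsim("checksum mismatch: archive is truncated or corrupted",
                "hcrsim_integrity_error")
  model <- jsonlite::unserializeJSON(doc$payload)
  class(model) <- "hcd_model"
  model
}
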