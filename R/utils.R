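# Internal helpers shared across the pipeline.

# Stable short identifier for an ontology path: 16 hex chars of a
# deterministic 128-bit hash of the path text. Machine- and run-independent.
path_code <- function(path) {
  vapply(path, function(p) substr(rlang::hash(p), 1L, 16L), character(1),
         USE.NAMES = FALSE)
}

# Sanitize one path segment: backslash, slash and control characters become
# "_"; segments are capped at 200 characters (warehouse path-length limits).
sanitize_segment <- function(x) {
  x <- gsub("[\\\\/[:cntrl:]]", "_", x)
  substr(x, 1L, 200L)
}

# Sanitize a key component for use inside a canonical subject/visit id.
sanitize_id <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]", "_", x)
  x
}

new_anomaly_log <- function() {
  tibble::tibble(
    stage  = character(),
    source = character(),
    row_id = integer(),
    kind   = character(),
    detail = character()
  )
}

log_anomaly <- function(log, stage, source, row_id, kind, detail) {
  dplyr::bind_rows(log, tibble::tibble(
    stage = stage, source = source,
    row_id = as.integer(row_id), kind = kind, detail = detail
  ))
}

is_missing_cell <- function(x) {
  is.na(x)
}

# Deterministic content checksum used in bundle manifests.
content_checksum <- function(text) {
  unname(vapply(text, rlang::hash, character(1)))
}

`%||%` <- rlang::`%||%`
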