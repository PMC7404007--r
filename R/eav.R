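# Denormalization of EAV-shaped tables and widening of declared-attribute
# tables into a common stream of attribute records.

# Per-row context shared by both record producers: subject keys, visit keys
# and the timestamp token, read off the table according to its binding.
row_context <- function(table, binding, tokens) {
  n <- nrow(table)
  get_keys <- function(cols) {
    if (length(cols) == 0) return(rep(NA_character_, n))
    vals <- lapply(cols, function(col)
      normalize_missing(table[[col]], tokens)$cells)
    any_na <- Reduce(`|`, lapply(vals, is.na))
    out <- do.call(paste, c(vals, sep = "\x1f"))
    out[any_na] <- NA_character_
    out
  }
  ts <- if (!is.null(binding$timestamp_column)) {
    normalize_missing(table[[binding$timestamp_column]], tokens)$cells
  } else {
    rep(NA_character_, n)
  }
  list(subject_key = get_keys(binding$key_columns),
       visit_key = get_keys(binding$visit_key_columns),
       timestamp_token = ts)
}

empty_records <- function() {
  tibble::tibble(
    entity = character(), attribute = character(),
    subject_key = character(), visit_key = character(),
    value = character(), meta = list(),
    timestamp_token = character(),
    source = character(), row_id = integer()
  )
}

meta_map_for_rows <- function(table, meta_defs, rows, tokens) {
  if (length(meta_defs) == 0) return(rep(list(character()), length(rows)))
  cols <- lapply(meta_defs, function(m)
    normalize_missing(table[[m$column]], tokens)$cells[rows])
  names(cols) <- map_chr(meta_defs, "name")
  lapply(seq_along(rows), function(i) {
    v <- vapply(cols, `[[`, character(1), i)
    v <- v[!is.na(v)]  # a missing meta cell means the key is absent
    if (length(v) == 0) character() else v
  })
}

#' Denormalize an EAV table into attribute records
#'
#' Produces one record per row whose parameter cell(s) and value cell are
#' all non-missing. The record's attribute name is the normalized parameter
#' label (multiple parameter columns joined with the entity's `label_join`);
#' meta-attribute values are read from the EAV block's meta columns on the
#' same row, with missing meta cells simply absent from the map. Rows
#' skipped for a missing parameter or missing value are counted by reason.
#' Value payloads pass through verbatim; typing happens later against the
#' column profiles.
#'
#' @param table A `source_table`.
#' @param entity An entity definition carrying an `eav` block bound to this
#'   table's source.
#' @param cfg The `staging_config` (for the source binding and missing
#'   tokens).
#' @return A list with `records` (tibble) and `skipped` (named counts:
#'   `missing_parameter`, `missing_value`).
#' @export
denormalize_eav <- function(table, entity, cfg) {
  stopifnot(inherits(table, "source_table"), !is.null(entity$eav))
  tokens <- cfg$options$missing_tokens
  binding <- cfg$sources[[entity$source]]
  eav <- entity$eav
  n <- nrow(table)
  if (n == 0) {
    return(list(records = empty_records(),
                skipped = c(missing_parameter = 0L, missing_value = 0L)))
  }

  pcells <- lapply(eav$parameter_columns, function(col)
    normalize_missing(normalize_parameter_label(table[[col]]), tokens)$cells)
  vcells <- normalize_missing(table[[eav$value_column]], tokens)$cells
  param_ok <- Reduce(`&`, lapply(pcells, function(x) !is.na(x)))
  value_ok <- !is.na(vcells)
  use <- param_ok & value_ok
  skipped <- c(missing_parameter = sum(!param_ok),
               missing_value = sum(param_ok & !value_ok))

  if (!any(use)) {
    return(list(records = empty_records(), skipped = skipped))
  }
  rows <- which(use)
  ctx <- row_context(table, binding, tokens)
  label <- do.call(paste, c(lapply(pcells, `[`, rows), sep = eav$label_join))

  records <- tibble::tibble(
    entity = entity$name,
    attribute = label,
    subject_key = ctx$subject_key[rows],
    visit_key = ctx$visit_key[rows],
    value = vcells[rows],
    meta = meta_map_for_rows(table, eav$meta_columns, rows, tokens),
    timestamp_token = ctx$timestamp_token[rows],
    source = source_logical_name(table),
    row_id = source_row_ids(table)[rows]
  )
  list(records = records, skipped = skipped)
}

#' Widen a declared-attribute table into attribute records
#'
#' For an entity without an EAV block: one record per (row, declared
#' attribute) pair whose cell is non-missing. Meta-attribute values come
#' from the attribute's own meta columns on the same row; an empty meta
#' cell leaves that key out of the record's map.
#'
#' @inheritParams denormalize_eav
#' @return A list with `records` (tibble) and `skipped` (named count
#'   `missing_value`: cells skipped for missingness).
#' @export
widen_declared <- function(table, entity, cfg) {
  stopifnot(inherits(table, "source_table"))
  tokens <- cfg$options$missing_tokens
  binding <- cfg$sources[[entity$source]]
  attrs <- keep(entity$attributes, ~ !.x$generated)
  n <- nrow(table)
  if (n == 0 || length(attrs) == 0) {
    return(list(records = empty_records(), skipped = c(missing_value = 0L)))
  }
  ctx <- row_context(table, binding, tokens)

  parts <- lapply(attrs, function(a) {
    cells <- normalize_missing(table[[a$column]], tokens)$cells
    rows <- which(!is.na(cells))
    if (length(rows) == 0) return(NULL)
    tibble::tibble(
      entity = entity$name,
      attribute = a$name,
      subject_key = ctx$subject_key[rows],
      visit_key = ctx$visit_key[rows],
      value = cells[rows],
      meta = meta_map_for_rows(table, a$meta, rows, tokens),
      timestamp_token = ctx$timestamp_token[rows],
      source = source_logical_name(table),
      row_id = source_row_ids(table)[rows]
    )
  })
  records <- dplyr::bind_rows(compact(parts))
  if (nrow(records) == 0) records <- empty_records()
  skipped <- n * length(attrs) - nrow(records)
  list(records = records, skipped = c(missing_value = as.integer(skipped)))
}
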