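# Missing-value normalization, column type inference, timestamp parsing
# with explicit precision, and declarative row filters.

#' Normalize missing-value tokens
#'
#' Any cell equal — after outer-whitespace trimming, case-insensitively —
#' to one of the configured tokens becomes `NA`, the canonical missing
#' marker used by the rest of the pipeline.
#'
#' @param cells Character vector of raw cells.
#' @param tokens Character vector of missing-value tokens; the default set
#'   is `"", "NA", "N/A", "NULL", "-", "."`.
#' @return A list with `cells` (normalized vector) and `missing_count`.
#' @export
normalize_missing <- function(cells, tokens = default_missing_tokens()) {
  stopifnot(length(tokens) > 0)
  if (length(cells) == 0) {
    return(list(cells = character(), missing_count = 0L))
  }
  trimmed <- tolower(str_trim(cells))
  hit <- trimmed %in% tolower(tokens) | is.na(cells)
  cells[hit] <- NA_character_
  list(cells = cells, missing_count = sum(hit))
}

# Strict numeric parse under one decimal-separator convention.
parse_numeric_cells <- function(cells, decimal = ".") {
  if (decimal == ",") {
    ok <- grepl("^[+-]?[0-9]+(,[0-9]+)?$", cells)
    out <- rep(NA_real_, length(cells))
    out[ok] <- as.numeric(gsub(",", ".", cells[ok], fixed = TRUE))
  } else {
    ok <- grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                cells)
    out <- rep(NA_real_, length(cells))
    out[ok] <- as.numeric(cells[ok])
  }
  out
}

#' Profile a column and infer its data type
#'
#' Applies the inference rules used throughout staging: a column is
#' `numeric` only when *all* non-missing cells parse under a single
#' decimal-separator convention (one stray string demotes the whole column —
#' silent coercion of clinical values is worse than a categorical fallback);
#' otherwise `date` when at least 95% of non-missing cells parse as
#' timestamps; otherwise `categorical` when the distinct count is at most
#' `max(20, 5%)` of the rows; otherwise free `text`. The decimal comma is
#' accepted only when no cell contains a dot and every numeric candidate
#' matches the digits-comma-digits pattern, avoiding thousands-separator
#' ambiguity.
#'
#' @param cells Character cells after missing normalization (`NA` = missing).
#' @param conventions Date conventions (see [parse_timestamp()]).
#' @return A `column_profile` list: `inferred_type`,
#'   `numeric_parse_fraction`, `date_parse_fraction`, `decimal_separator`,
#'   `distinct_count`, `missing_count`, `winning_date_formats`.
#' @export
profile_column <- function(cells, conventions = list(day_first = TRUE,
                                                     date_formats = character())) {
  n_missing <- sum(is.na(cells))
  obs <- cells[!is.na(cells)]
  n <- length(obs)
  distinct <- length(unique(obs))

  profile <- function(type, num_frac, date_frac, dec, formats = character()) {
    structure(list(inferred_type = type,
                   numeric_parse_fraction = num_frac,
                   date_parse_fraction = date_frac,
                   decimal_separator = dec,
                   distinct_count = distinct,
                   missing_count = n_missing,
                   winning_date_formats = formats),
              class = "column_profile")
  }
  if (n == 0) return(profile("text", 0, 0, "."))

  dot_frac <- mean(!is.na(parse_numeric_cells(obs, ".")))
  comma_ok <- !any(grepl(".", obs, fixed = TRUE)) &&
    all(grepl("^[+-]?[0-9]+(,[0-9]+)?$", obs))
  if (dot_frac == 1) {
    return(profile("numeric", 1, 0, "."))
  }
  if (comma_ok) {
    return(profile("numeric", 1, 0, ","))
  }

  ts <- lapply(obs, function(x) parse_timestamp_quiet(x, conventions))
  date_frac <- mean(!vapply(ts, is.null, logical(1)))
  if (date_frac >= 0.95) {
    fmts <- unique(unlist(lapply(ts, function(t) t$format)))
    return(profile("date", dot_frac, date_frac, ".", fmts))
  }

  ceiling_ <- max(20, ceiling(0.05 * length(cells)))
  if (distinct <= ceiling_) {
    return(profile("categorical", dot_frac, date_frac, "."))
  }
  profile("text", dot_frac, date_frac, ".")
}

# All timestamp patterns tried, in order. ISO-8601 shapes come first; the
# configured locale formats (default day-first dotted/slashed) after.
timestamp_patterns <- function(conventions) {
  day_first <- isTRUE(conventions$day_first)
  base <- list(
    list(rx = "^(\\d{4})-(\\d{2})-(\\d{2})[T ](\\d{2}):(\\d{2}):(\\d{2})$",
         order = c("Y", "m", "d", "H", "M", "S"), precision = "second",
         format = "ISO second"),
    list(rx = "^(\\d{4})-(\\d{2})-(\\d{2})[T ](\\d{2}):(\\d{2})$",
         order = c("Y", "m", "d", "H", "M"), precision = "minute",
         format = "ISO minute"),
    list(rx = "^(\\d{4})-(\\d{2})-(\\d{2})$",
         order = c("Y", "m", "d"), precision = "day", format = "ISO day"),
    list(rx = "^(\\d{4})-(\\d{2})$",
         order = c("Y", "m"), precision = "month", format = "ISO month"),
    list(rx = "^(\\d{4})$",
         order = "Y", precision = "year", format = "ISO year")
  )
  dmy <- list(
    list(rx = "^(\\d{1,2})\\.(\\d{1,2})\\.(\\d{4}) (\\d{2}):(\\d{2}):(\\d{2})$",
         order = c("d", "m", "Y", "H", "M", "S"), precision = "second",
         format = "dotted second"),
    list(rx = "^(\\d{1,2})\\.(\\d{1,2})\\.(\\d{4}) (\\d{2}):(\\d{2})$",
         order = c("d", "m", "Y", "H", "M"), precision = "minute",
         format = "dotted minute"),
    list(rx = "^(\\d{1,2})\\.(\\d{1,2})\\.(\\d{4})$",
         order = c("d", "m", "Y"), precision = "day", format = "dotted day"),
    list(rx = "^(\\d{1,2})/(\\d{1,2})/(\\d{4})$",
         order = c("d", "m", "Y"), precision = "day", format = "slashed day"),
    list(rx = "^(\\d{1,2})\\.(\\d{4})$",
         order = c("m", "Y"), precision = "month", format = "dotted month")
  )
  if (!day_first) {
    dmy <- lapply(dmy, function(p) {
      p$order[p$order == "d"] <- "_d"
      p$order[p$order == "m"] <- "d"
      p$order[p$order == "_d"] <- "m"
      p
    })
  }
  c(base, dmy)
}

parse_timestamp_quiet <- function(token, conventions = list(day_first = TRUE)) {
  token <- str_trim(token)
  for (p in timestamp_patterns(conventions)) {
    m <- regmatches(token, regexec(p$rx, token))[[1]]
    if (length(m) == 0) next
    parts <- setNames(as.integer(m[-1]), p$order)
    y <- parts[["Y"]]
    mo <- if ("m" %in% names(parts)) parts[["m"]] else 1L
    d <- if ("d" %in% names(parts)) parts[["d"]] else 1L
    H <- if ("H" %in% names(parts)) parts[["H"]] else 0L
    Mi <- if ("M" %in% names(parts)) parts[["M"]] else 0L
    S <- if ("S" %in% names(parts)) parts[["S"]] else 0L
    if (mo < 1 || mo > 12 || d < 1 || d > 31 || H > 23 || Mi > 59 || S > 60)
      next
    instant <- tryCatch(
      as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                         y, mo, d, H, Mi, S), tz = "UTC"),
      error = function(e) as.POSIXct(NA))
    if (is.na(instant)) next  # e.g. Feb 30
    # reject normalized overflow dates (Apr 31 -> May 1)
    if (as.integer(format(instant, "%d", tz = "UTC")) != d) next
    return(list(instant = instant, precision = p$precision,
                original = token, format = p$format))
  }
  NULL
}

#' Parse a timestamp token with explicit precision
#'
#' ISO-8601 shapes are tried first, then locale formats (dotted and slashed
#' numeric dates, day-first by default). The precision field records the
#' granularity actually present in the token — `"2019"` parses at year
#' precision, `"2019-03"` at month precision — and the instant returned is
#' the *start of the precision window* (January 1st, first of the month,
#' midnight), so downstream emitters can disclose exactly how much of a
#' timestamp is imputed rather than observed.
#'
#' @param token A non-missing text token.
#' @param conventions List with `day_first` (default `TRUE`) and optional
#'   extra `date_formats`.
#' @return A `timestamp` list: `instant` (POSIXct, UTC), `precision` (one of
#'   year, month, day, minute, second), `original`, `format`; or an error of
#'   class `clinstage_timestamp_error` for unparseable tokens.
#' @export
parse_timestamp <- function(token, conventions = list(day_first = TRUE)) {
  out <- parse_timestamp_quiet(token, conventions)
  if (is.null(out)) {
    abort(paste0("unparseable timestamp token: `", token, "`"),
          class = "clinstage_timestamp_error")
  }
  structure(out, class = "timestamp")
}

# Render an instant back at a given precision (used by emitters and the
# round-trip property test).
format_timestamp <- function(instant, precision) {
  fmt <- switch(precision,
                year = "%Y", month = "%Y-%m", day = "%Y-%m-%d",
                minute = "%Y-%m-%d %H:%M", second = "%Y-%m-%d %H:%M:%S")
  format(instant, fmt, tz = "UTC")
}

#' Apply declarative row filters to a source table
#'
#' Each filter names a source, a column, a predicate (`equals`, `in-set`,
#' `numeric-range`, `non-missing`) and an action (`keep` or `drop`).
#' Surviving rows satisfy every keep-predicate and no drop-predicate.
#' Filters bound to other sources are ignored. Removal counts per filter
#' are returned for the run report.
#'
#' @param table A `source_table`.
#' @param filters List of filter specs (from a `staging_config`).
#' @param tokens Missing-value tokens used by the `non-missing` predicate.
#' @return A list with `table` (filtered `source_table`), `rows_removed`,
#'   and `per_filter` (tibble of removal counts).
#' @export
apply_filters <- function(table, filters,
                          tokens = default_missing_tokens()) {
  stopifnot(inherits(table, "source_table"))
  lname <- source_logical_name(table)
  filters <- keep(filters, ~ is.null(.x$source) || identical(.x$source, lname))
  if (length(filters) == 0) {
    return(list(table = table, rows_removed = 0L,
                per_filter = tibble::tibble(column = character(),
                                            predicate = character(),
                                            removed = integer())))
  }
  keep_mask <- rep(TRUE, nrow(table))
  per <- list()
  for (f in filters) {
    cells <- normalize_missing(table[[f$column]], tokens)$cells
    sat <- switch(f$predicate,
      "equals" = !is.na(cells) & cells == f$values[1],
      "in-set" = !is.na(cells) & cells %in% f$values,
      "non-missing" = !is.na(cells),
      "numeric-range" = {
        num <- parse_numeric_cells(ifelse(is.na(cells), "x", cells))
        ok <- !is.na(num)
        if (!is.null(f$min)) ok <- ok & num >= f$min
        if (!is.null(f$max)) ok <- ok & num <= f$max
        ok
      })
    this_keep <- if (f$action == "keep") sat else !sat
    removed_here <- sum(keep_mask & !this_keep)
    per[[length(per) + 1L]] <- tibble::tibble(
      column = f$column, predicate = f$predicate,
      removed = as.integer(removed_here))
    keep_mask <- keep_mask & this_keep
  }
  out <- table[keep_mask, , drop = FALSE]
  out <- new_source_table(out, logical_name = lname,
                          provenance = attr(table, "provenance"),
                          row_ids = source_row_ids(table)[keep_mask],
                          ingest_log = source_ingest_log(table))
  list(table = out, rows_removed = as.integer(sum(!keep_mask)),
       per_filter = dplyr::bind_rows(per))
}
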