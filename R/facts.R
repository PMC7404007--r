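# Canonical subject / visit / fact model: key resolution, visit linkage,
# value typing, duplicate detection.

KEY_SEP <- "\x1f"

canonical_id <- function(prefix, key) {
  paste0(prefix, "_",
         vapply(strsplit(key, KEY_SEP, fixed = TRUE),
                function(p) paste(sanitize_id(p), collapse = "_"),
                character(1)))
}

study_code_of <- function(cfg) {
  cfg$options$study_code %||% toupper(sanitize_id(cfg$study_label))
}

#' Build subjects from the patient file
#'
#' One subject per distinct (composite) key tuple. Rows repeating a key are
#' merged; a repeated key with contradictory non-key cells keeps the first
#' observed value and logs a conflict. Rows with any missing key cell are
#' rejected and logged. Canonical subject ids are the sanitized key values
#' joined by `"_"`, prefixed with the study code — stable across runs.
#'
#' @param patient_table The `source_table` with role patient-file.
#' @param cfg The `staging_config`.
#' @return A list: `subjects` (tibble with `subject_id`, `subject_key` and
#'   one character column per non-key patient column), `conflicts` (tibble),
#'   `rejected` (tibble of row ids and reasons).
#' @export
build_subjects <- function(patient_table, cfg) {
  stopifnot(inherits(patient_table, "source_table"))
  tokens <- cfg$options$missing_tokens
  binding <- cfg$sources[[source_logical_name(patient_table)]]
  key_cols <- binding$key_columns
  stopifnot(length(key_cols) > 0)

  keys <- lapply(key_cols, function(col)
    normalize_missing(patient_table[[col]], tokens)$cells)
  key_ok <- Reduce(`&`, lapply(keys, function(x) !is.na(x)))
  key <- do.call(paste, c(keys, sep = KEY_SEP))
  key[!key_ok] <- NA_character_

  rejected <- tibble::tibble(
    row_id = source_row_ids(patient_table)[!key_ok],
    reason = rep("missing-subject-key", sum(!key_ok)))

  df <- tibble::as_tibble(unclass_source_table(patient_table))
  df[] <- lapply(df, function(col) normalize_missing(col, tokens)$cells)
  df$.key <- key
  df <- df[key_ok, , drop = FALSE]
  other_cols <- setdiff(names(df), c(key_cols, ".key"))

  conflicts <- list()
  first <- !duplicated(df$.key)
  if (any(!first)) {
    firsts <- df[first, , drop = FALSE]
    for (i in which(!first)) {
      ref <- firsts[match(df$.key[i], firsts$.key), , drop = FALSE]
      for (col in other_cols) {
        a <- ref[[col]][1]; b <- df[[col]][i]
        if (!identical(a, b) && !(is.na(a) && is.na(b))) {
          conflicts[[length(conflicts) + 1L]] <- tibble::tibble(
            subject_key = df$.key[i], column = col,
            kept = a %||% NA_character_, discarded = b,
            resolution = "keep-first")
        }
      }
    }
  }
  subjects <- df[first, , drop = FALSE]
  out <- tibble::tibble(
    subject_id = canonical_id(study_code_of(cfg), subjects$.key),
    subject_key = subjects$.key)
  for (col in other_cols) out[[col]] <- subjects[[col]]
  list(subjects = out,
       conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts) else
         tibble::tibble(subject_key = character(), column = character(),
                        kept = character(), discarded = character(),
                        resolution = character()),
       rejected = rejected)
}

#' Build visits from the (optional) visit file
#'
#' Visits are linked to subjects via the patient key columns, which must be
#' present in the visit file under the same names. Start and end timestamps
#' come from the binding's `timestamp_column` / `end_timestamp_column`.
#' A visit whose end precedes its start is rejected as an inconsistent
#' timestamp; a visit referencing an unknown subject is rejected as an
#' orphan. When no visit file is configured the pipeline simply proceeds
#' with an empty visit list.
#'
#' @param visit_table A `source_table`, or `NULL` when no visit file exists.
#' @param cfg The `staging_config`.
#' @param subjects The subjects tibble from [build_subjects()].
#' @return A list: `visits` (tibble: `visit_id`, `visit_key`, `subject_id`,
#'   `start`, `start_precision`, `end`, `end_precision`), `rejected`
#'   (tibble of row ids and reasons).
#' @export
build_visits <- function(visit_table, cfg, subjects) {
  empty <- tibble::tibble(
    visit_id = character(), visit_key = character(), subject_id = character(),
    start = as.POSIXct(character(), tz = "UTC"), start_precision = character(),
    end = as.POSIXct(character(), tz = "UTC"), end_precision = character())
  if (is.null(visit_table)) {
    return(list(visits = empty,
                rejected = tibble::tibble(row_id = integer(),
                                          reason = character())))
  }
  tokens <- cfg$options$missing_tokens
  binding <- cfg$sources[[source_logical_name(visit_table)]]
  conventions <- list(day_first = cfg$options$day_first)

  vkeys <- lapply(binding$key_columns, function(col)
    normalize_missing(visit_table[[col]], tokens)$cells)
  skeys <- lapply(cfg$subject_key, function(col)
    normalize_missing(visit_table[[col]], tokens)$cells)
  v_ok <- Reduce(`&`, lapply(vkeys, function(x) !is.na(x)))
  s_ok <- Reduce(`&`, lapply(skeys, function(x) !is.na(x)))
  vkey <- do.call(paste, c(vkeys, sep = KEY_SEP))
  skey <- do.call(paste, c(skeys, sep = KEY_SEP))

  n <- nrow(visit_table)
  row_ids <- source_row_ids(visit_table)
  start_tok <- if (!is.null(binding$timestamp_column)) {
    normalize_missing(visit_table[[binding$timestamp_column]], tokens)$cells
  } else rep(NA_character_, n)
  end_tok <- if (!is.null(binding$end_timestamp_column)) {
    normalize_missing(visit_table[[binding$end_timestamp_column]], tokens)$cells
  } else rep(NA_character_, n)

  parse_tok <- function(tok) {
    if (is.na(tok)) return(list(instant = as.POSIXct(NA, tz = "UTC"),
                                precision = NA_character_, failed = FALSE))
    p <- parse_timestamp_quiet(tok, conventions)
    if (is.null(p)) return(list(instant = as.POSIXct(NA, tz = "UTC"),
                                precision = NA_character_, failed = TRUE))
    list(instant = p$instant, precision = p$precision, failed = FALSE)
  }
  starts <- lapply(start_tok, parse_tok)
  ends <- lapply(end_tok, parse_tok)

  rejected <- list()
  keep_row <- rep(TRUE, n)
  for (i in seq_len(n)) {
    reason <- NULL
    if (!v_ok[i] || !s_ok[i]) {
      reason <- "missing-visit-key"
    } else if (!skey[i] %in% subjects$subject_key) {
      reason <- "orphan-visit-unknown-subject"
    } else if (starts[[i]]$failed || ends[[i]]$failed) {
      reason <- "unparseable-timestamp"
    } else if (!is.na(starts[[i]]$instant) && !is.na(ends[[i]]$instant) &&
               ends[[i]]$instant < starts[[i]]$instant) {
      reason <- "inconsistent-timestamp-end-before-start"
    }
    if (!is.null(reason)) {
      keep_row[i] <- FALSE
      rejected[[length(rejected) + 1L]] <- tibble::tibble(
        row_id = row_ids[i], reason = reason)
    }
  }
  idx <- which(keep_row)
  dup <- duplicated(vkey[idx])
  for (i in idx[dup]) {
    rejected[[length(rejected) + 1L]] <- tibble::tibble(
      row_id = row_ids[i], reason = "duplicate-visit-key")
  }
  idx <- idx[!dup]

  visits <- tibble::tibble(
    visit_id = canonical_id(paste0(study_code_of(cfg), "_V"), vkey[idx]),
    visit_key = vkey[idx],
    subject_id = subjects$subject_id[match(skey[idx], subjects$subject_key)],
    start = as.POSIXct(vapply(starts[idx], function(p)
      as.numeric(p$instant), numeric(1)), origin = "1970-01-01", tz = "UTC"),
    start_precision = vapply(starts[idx], function(p)
      p$precision %||% NA_character_, character(1)),
    end = as.POSIXct(vapply(ends[idx], function(p)
      as.numeric(p$instant), numeric(1)), origin = "1970-01-01", tz = "UTC"),
    end_precision = vapply(ends[idx], function(p)
      p$precision %||% NA_character_, character(1)))
  list(visits = visits,
       rejected = if (length(rejected)) dplyr::bind_rows(rejected) else
         tibble::tibble(row_id = integer(), reason = character()))
}

# End of the precision window that starts at `instant` (used when a visit
# has no explicit end: the visit then spans its start token's granularity).
precision_window_end <- function(instant, precision) {
  switch(precision,
    year = seq(instant, by = "1 year", length.out = 2)[2] - 1,
    month = seq(instant, by = "1 month", length.out = 2)[2] - 1,
    day = instant + 86399,
    minute = instant + 59,
    second = instant)
}

# Profile every (entity, attribute) over its record values. EAV attributes
# share a physical value column, so typing must be decided per attribute,
# not per column.
profile_attributes <- function(records, conventions) {
  if (nrow(records) == 0) return(list())
  split_idx <- split(seq_len(nrow(records)),
                     paste(records$entity, records$attribute, sep = KEY_SEP))
  lapply(split_idx, function(ix)
    profile_column(records$value[ix], conventions))
}

concept_path_for <- function(study, entity, attribute) {
  paste0("\\", sanitize_segment(study), "\\", sanitize_segment(entity),
         "\\", sanitize_segment(attribute), "\\")
}

meta_signature <- function(meta) {
  vapply(meta, function(m) {
    if (length(m) == 0) return("")
    m <- m[order(names(m), method = "radix")]
    paste(names(m), m, sep = "=", collapse = ";")
  }, character(1))
}

#' Assemble typed facts from attribute records
#'
#' Resolves each record's subject key against the subject registry (unknown
#' subjects are rejected and logged), links the record to a visit — by visit
#' key when present, otherwise by timestamp containment within exactly one
#' of the subject's visit windows (zero or two-plus candidate windows leave
#' the fact unlinked; ambiguity is logged, never guessed) — and types the
#' value according to its attribute profile. Numeric values are stored
#' decimal-normalized with `"."`. Facts whose key-linked timestamp falls
#' outside every visit window are kept but logged as timestamp warnings.
#'
#' @param records Attribute-record tibble ([denormalize_eav()] /
#'   [widen_declared()]).
#' @param subjects Subjects tibble.
#' @param visits Visits tibble.
#' @param profiles Attribute profiles from `profile_attributes()`; computed
#'   on the fly when `NULL`.
#' @param cfg The `staging_config`.
#' @return A list: `facts` (tibble), `rejected` (tibble), `warnings`
#'   (anomaly tibble).
#' @export
assemble_facts <- function(records, subjects, visits, profiles = NULL, cfg) {
  conventions <- list(day_first = cfg$options$day_first)
  profiles <- profiles %||% profile_attributes(records, conventions)
  study <- cfg$study_label
  n <- nrow(records)
  empty_facts <- tibble::tibble(
    subject_id = character(), visit_id = character(), entity = character(),
    attribute = character(), concept_path = character(),
    value_type = character(), value_num = numeric(), value_chr = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    ts_precision = character(), meta = list(), meta_sig = character(),
    source = character(), row_id = integer())
  if (n == 0) {
    return(list(facts = empty_facts,
                rejected = tibble::tibble(row_id = integer(),
                                          source = character(),
                                          reason = character()),
                warnings = new_anomaly_log()))
  }

  subj_id <- subjects$subject_id[match(records$subject_key,
                                       subjects$subject_key)]
  known <- !is.na(subj_id) & !is.na(records$subject_key)
  rejected <- tibble::tibble(
    row_id = records$row_id[!known],
    source = records$source[!known],
    reason = ifelse(is.na(records$subject_key[!known]),
                    "missing-subject-key", "unknown-subject-key"))
  warnings <- new_anomaly_log()

  rec <- records[known, , drop = FALSE]
  subj_id <- subj_id[known]

  ts <- lapply(rec$timestamp_token, function(tok) {
    if (is.na(tok)) return(NULL)
    parse_timestamp_quiet(tok, conventions)
  })
  bad_ts <- !is.na(rec$timestamp_token) & vapply(ts, is.null, logical(1))
  for (i in which(bad_ts)) {
    warnings <- log_anomaly(warnings, "facts", rec$source[i], rec$row_id[i],
                            "unparseable-timestamp",
                            paste0("token `", rec$timestamp_token[i],
                                   "` not parseable; fact kept untimed"))
  }
  instant <- as.POSIXct(vapply(ts, function(p)
    if (is.null(p)) NA_real_ else as.numeric(p$instant), numeric(1)),
    origin = "1970-01-01", tz = "UTC")
  precision <- vapply(ts, function(p)
    if (is.null(p)) NA_character_ else p$precision, character(1))

  # visit linkage
  visit_id <- rep(NA_character_, nrow(rec))
  if (nrow(visits) > 0) {
    by_key <- match(rec$visit_key, visits$visit_key)
    key_linked <- !is.na(rec$visit_key) & !is.na(by_key)
    visit_id[key_linked] <- visits$visit_id[by_key[key_linked]]

    win_end <- as.POSIXct(mapply(function(e, s, sp) {
      if (!is.na(e)) return(as.numeric(e))
      if (is.na(s)) return(NA_real_)
      as.numeric(precision_window_end(s, sp))
    }, visits$end, visits$start, visits$start_precision),
    origin = "1970-01-01", tz = "UTC")

    need_ts_link <- !key_linked & !is.na(instant)
    for (i in which(need_ts_link)) {
      cand <- which(visits$subject_id == subj_id[i] &
                      !is.na(visits$start) &
                      visits$start <= instant[i] & instant[i] <= win_end)
      if (length(cand) == 1) {
        visit_id[i] <- visits$visit_id[cand]
      } else if (length(cand) >= 2) {
        warnings <- log_anomaly(warnings, "facts", rec$source[i],
                                rec$row_id[i], "ambiguous-visit-linkage",
                                paste0("timestamp falls in ", length(cand),
                                       " visit windows; fact left unlinked"))
      }
    }
    # consistency check on key-linked facts with timestamps
    for (i in which(key_linked & !is.na(instant))) {
      v <- by_key[i]
      if (!is.na(visits$start[v]) &&
          (instant[i] < visits$start[v] || instant[i] > win_end[v])) {
        warnings <- log_anomaly(warnings, "facts", rec$source[i],
                                rec$row_id[i], "timestamp-outside-visit",
                                "fact timestamp outside its key-linked visit window")
      }
    }
  }

  pkey <- paste(rec$entity, rec$attribute, sep = KEY_SEP)
  vtype <- vapply(pkey, function(k) {
    p <- profiles[[k]]
    if (is.null(p)) "text" else p$inferred_type
  }, character(1), USE.NAMES = FALSE)
  dec <- vapply(pkey, function(k) {
    p <- profiles[[k]]
    if (is.null(p)) "." else p$decimal_separator
  }, character(1), USE.NAMES = FALSE)
  value_num <- rep(NA_real_, nrow(rec))
  num_rows <- vtype == "numeric"
  if (any(num_rows)) {
    value_num[num_rows] <- mapply(function(v, d)
      parse_numeric_cells(v, d), rec$value[num_rows], dec[num_rows])
  }
  value_chr <- ifelse(num_rows,
                      vapply(value_num, function(x)
                        format(x, trim = TRUE, scientific = FALSE),
                        character(1)),
                      rec$value)

  facts <- tibble::tibble(
    subject_id = subj_id,
    visit_id = visit_id,
    entity = rec$entity,
    attribute = rec$attribute,
    concept_path = concept_path_for(study, rec$entity, rec$attribute),
    value_type = vtype,
    value_num = value_num,
    value_chr = value_chr,
    timestamp = instant,
    ts_precision = precision,
    meta = rec$meta,
    meta_sig = meta_signature(rec$meta),
    source = rec$source,
    row_id = rec$row_id)
  list(facts = facts, rejected = rejected, warnings = warnings)
}

#' Detect and resolve duplicate facts
#'
#' Two facts are exact duplicates when subject, visit, concept path,
#' timestamp, value *and* modifier map all coincide — two lab results
#' differing only in unit are distinct facts. Exact duplicates collapse to
#' one. Facts agreeing on everything but the value are conflicts, resolved
#' per policy (default `keep-first` in provenance order, with a conflict
#' entry per discarded value).
#'
#' @param facts Facts tibble.
#' @param policy `"keep-first"` (default) or `"keep-all-conflicts"` (keep
#'   conflicting values as separate facts; only exact duplicates collapse).
#' @return A list: `facts`, `report` (a `dedup_report`:
#'   `exact_duplicates_dropped`, `conflicts` tibble, `policy`).
#' @export
deduplicate_facts <- function(facts, policy = "keep-first") {
  ts_chr <- ifelse(is.na(facts$timestamp), "",
                   paste(format(facts$timestamp,
                                "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                         facts$ts_precision))
  base_key <- paste(facts$subject_id,
                    ifelse(is.na(facts$visit_id), "", facts$visit_id),
                    facts$concept_path, ts_chr, facts$meta_sig,
                    sep = KEY_SEP)
  full_key <- paste(base_key, facts$value_chr, sep = KEY_SEP)

  exact_dup <- duplicated(full_key)
  n_exact <- sum(exact_dup)
  facts1 <- facts[!exact_dup, , drop = FALSE]
  bkey1 <- base_key[!exact_dup]

  conflicts <- tibble::tibble(
    subject_id = character(), concept_path = character(),
    kept = character(), discarded = character(), resolution = character())
  if (policy == "keep-first") {
    conf <- duplicated(bkey1)
    if (any(conf)) {
      firsts <- facts1[!duplicated(bkey1), , drop = FALSE]
      fkey <- bkey1[!duplicated(bkey1)]
      for (i in which(conf)) {
        j <- match(bkey1[i], fkey)
        conflicts <- dplyr::bind_rows(conflicts, tibble::tibble(
          subject_id = facts1$subject_id[i],
          concept_path = facts1$concept_path[i],
          kept = firsts$value_chr[j],
          discarded = facts1$value_chr[i],
          resolution = "keep-first"))
      }
      facts1 <- facts1[!conf, , drop = FALSE]
    }
  }
  report <- structure(list(exact_duplicates_dropped = n_exact,
                           conflicts = conflicts, policy = policy),
                      class = "dedup_report")
  list(facts = facts1, report = report)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat("<dedup_report> policy:", x$policy,
      "| exact duplicates dropped:", x$exact_duplicates_dropped,
      "| conflicts:", nrow(x$conflicts), "\n")
  invisible(x)
}
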