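# Compilation of the canonical model into the two back-end staging
# dialects: an i2b2-oriented batch-loader bundle and a tranSMART-oriented
# directory bundle. Both are tab-separated, UTF-8, LF.

tsv_cell <- function(x) {
  x <- ifelse(is.na(x), "", x)
  gsub("[\t\r\n]", " ", x)
}

tsv_text <- function(df) {
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) return(paste0(header, "\n"))
  body <- do.call(paste, c(lapply(df, tsv_cell), list(sep = "\t")))
  paste0(header, "\n", paste(body, collapse = "\n"), "\n")
}

fmt_ts <- function(instant, precision) {
  ifelse(is.na(instant) | is.na(precision), "",
         mapply(function(i, p) if (is.na(p)) "" else format_timestamp(i, p),
                instant, precision))
}

new_bundle <- function(dialect, files, counts, invocation,
                       aggregation = NULL) {
  structure(list(
    dialect = dialect,
    files = files,
    manifest = list(dialect = dialect, counts = counts,
                    checksums = lapply(files, rlang::hash)),
    invocation = invocation,
    aggregation = aggregation
  ), class = "staging_bundle")
}

#' @export
print.staging_bundle <- function(x, ...) {
  cat("<staging_bundle> dialect:", x$dialect, "|", length(x$files),
      "file(s) |", paste(names(x$manifest$counts),
                         unlist(x$manifest$counts), collapse = ", "), "\n")
  invisible(x)
}

ontology_file_df <- function(tree) {
  tibble::tibble(level = tree$level, full_path = tree$full_path,
                 name = tree$name, kind = tree$kind,
                 value_type = tree$value_type, code = tree$code)
}

#' Emit the i2b2-oriented staging bundle
#'
#' Compiles the canonical model into the file set an i2b2 batch loader
#' consumes: a subject file; a separate visit file (visit data are written
#' separately in this dialect) when visits exist; one fact file per entity
#' in long observation form, where each fact contributes a value row
#' (modifier code `@`) plus one row per meta-attribute value carrying the
#' coded ontology modifier node, tied together by an instance number; a
#' column-mapping and word-mapping file per fact file; the ontology file
#' with node codes; and an invocation descriptor recording that ontology
#' loading must precede fact loading. This dialect is lossless: every fact,
#' modifier and repeated timestamped value is preserved.
#'
#' @param subjects,visits,facts Model tibbles (deduplicated facts).
#' @param tree The coded `ontology`.
#' @param cfg The `staging_config`.
#' @return A `staging_bundle`.
#' @export
emit_i2b2_bundle <- function(subjects, visits, facts, tree, cfg) {
  if (nrow(subjects) == 0) {
    abort("no subjects in model; nothing loadable", class = "clinstage_emit_error")
  }
  if (nrow(facts) == 0) {
    warn("no facts in model; emitting metadata-only bundle")
  }
  files <- list()

  subj_df <- subjects
  subj_df$subject_key <- NULL
  files[["subjects.tsv"]] <- tsv_text(subj_df)

  if (nrow(visits) > 0) {
    files[["visits.tsv"]] <- tsv_text(tibble::tibble(
      visit_id = visits$visit_id, subject_id = visits$subject_id,
      start = fmt_ts(visits$start, visits$start_precision),
      start_precision = ifelse(is.na(visits$start_precision), "",
                               visits$start_precision),
      end = fmt_ts(visits$end, visits$end_precision),
      end_precision = ifelse(is.na(visits$end_precision), "",
                             visits$end_precision)))
  }

  code_of <- setNames(tree$code, tree$full_path)
  fact_cols <- c("subject_id", "visit_id", "concept_cd", "concept_path",
                 "instance_num", "modifier_cd", "value_type", "value",
                 "timestamp", "ts_precision")
  entities <- map_chr(cfg$entities, "name")
  for (ename in entities) {
    f <- facts[facts$entity == ename, , drop = FALSE]
    fname <- paste0("facts_", sanitize_id(ename), ".tsv")
    if (nrow(f) == 0) {
      empty <- tibble::as_tibble(setNames(
        rep(list(character()), length(fact_cols)), fact_cols))
      files[[fname]] <- tsv_text(empty)
    } else {
      inst <- seq_len(nrow(f))
      value_rows <- tibble::tibble(
        subject_id = f$subject_id, visit_id = f$visit_id,
        concept_cd = unname(code_of[f$concept_path]),
        concept_path = f$concept_path,
        instance_num = as.character(inst), modifier_cd = "@",
        value_type = f$value_type, value = f$value_chr,
        timestamp = fmt_ts(f$timestamp, f$ts_precision),
        ts_precision = ifelse(is.na(f$ts_precision), "", f$ts_precision))
      mod_rows <- list()
      for (i in inst) {
        m <- f$meta[[i]]
        if (length(m) == 0) next
        mpaths <- paste0(f$concept_path[i], sanitize_segment(names(m)), "\\")
        mod_rows[[length(mod_rows) + 1L]] <- tibble::tibble(
          subject_id = f$subject_id[i], visit_id = f$visit_id[i],
          concept_cd = unname(code_of[f$concept_path[i]]),
          concept_path = f$concept_path[i],
          instance_num = as.character(i),
          modifier_cd = unname(code_of[mpaths]),
          value_type = "text", value = unname(m),
          timestamp = fmt_ts(f$timestamp[i], f$ts_precision[i])[1],
          ts_precision = ifelse(is.na(f$ts_precision[i]), "",
                                f$ts_precision[i]))
      }
      files[[fname]] <- tsv_text(dplyr::bind_rows(c(list(value_rows),
                                                    mod_rows)))
    }
    files[[paste0("mapping_", sanitize_id(ename), ".tsv")]] <- tsv_text(
      tibble::tibble(
        filename = fname,
        category_path = paste0("\\", sanitize_segment(cfg$study_label),
                               "\\", sanitize_segment(ename), "\\"),
        column_index = as.character(seq_along(fact_cols)),
        label = fact_cols))
  }
  files[["word_mapping.tsv"]] <- tsv_text(
    tibble::tibble(filename = character(), column_index = character(),
                   original = character(), mapped = character()))
  files[["ontology.tsv"]] <- tsv_text(ontology_file_df(tree))

  invocation <- paste0(
    "backend: transmart-batch (i2b2 mode)\n",
    "order: 1) load ontology.tsv into the ontology cell; ",
    "2) load facts_*.tsv (fact loading must be preceded by loading the ",
    "ontology tree)\n",
    "subject file: subjects.tsv\n",
    if (nrow(visits) > 0) "visit file: visits.tsv\n" else "",
    "mapping files: mapping_*.tsv; word mapping: word_mapping.tsv\n")
  files[["invocation.txt"]] <- invocation

  new_bundle("i2b2-batch", files,
             counts = list(subjects = nrow(subjects), visits = nrow(visits),
                           facts = nrow(facts)),
             invocation = invocation)
}

# Declared meta-name order per (entity, attribute), for variant labels.
meta_order_map <- function(cfg) {
  out <- list()
  for (e in cfg$entities) {
    for (a in e$attributes) {
      out[[paste(e$name, a$name, sep = KEY_SEP)]] <- map_chr(a$meta, "name")
    }
  }
  out
}

transmart_variant_label <- function(attribute, meta, meta_names) {
  if (length(meta_names) == 0) return(attribute)
  vals <- vapply(meta_names, function(nm)
    if (nm %in% names(meta)) meta[[nm]] else "n/a", character(1))
  if (all(vals == "n/a")) return(attribute)
  paste0(attribute, " (", paste(vals, collapse = ", "), ")")
}

#' Emit the tranSMART-oriented staging bundle
#'
#' Compiles the model into the directory convention a tranSMART loader
#' expects: a study folder containing one clinical data file plus column-
#' and word-mapping files. tranSMART has no native meta-attribute or
#' time-series support, so meta-attributes are flattened into attribute
#' *variants* (label = attribute name followed by the meta values in
#' declared meta order, `n/a` for a missing value) and multiple values per
#' (subject, visit, variable) are collapsed per policy — default `latest`
#' timestamp, provenance-order first on ties; alternatives `first` and
#' `mean` (numeric variables only). Every collapse is counted in the
#' aggregation report, so the fact loss relative to the i2b2 dialect is
#' exactly reconciled.
#'
#' @param subjects,facts Model tibbles (deduplicated facts).
#' @param tree The coded `ontology`.
#' @param cfg The `staging_config`.
#' @param policy Aggregation policy; defaults to the configured
#'   `transmart_aggregation` option.
#' @return A list: `bundle` (a `staging_bundle`), `aggregation` (an
#'   `aggregation_report` with per-cell collapse counts and the policy).
#' @export
emit_transmart_bundle <- function(subjects, facts, tree, cfg,
                                  policy = NULL) {
  policy <- policy %||% cfg$options$transmart_aggregation
  if (nrow(subjects) == 0) {
    abort("no subjects in model; nothing loadable", class = "clinstage_emit_error")
  }
  study <- sanitize_id(cfg$study_label)
  morder <- meta_order_map(cfg)

  n <- nrow(facts)
  if (n > 0) {
    meta_names <- morder[paste(facts$entity, facts$attribute, sep = KEY_SEP)]
    variable <- vapply(seq_len(n), function(i)
      transmart_variant_label(facts$attribute[i], facts$meta[[i]],
                              meta_names[[i]] %||% character()),
      character(1))
    cell <- tibble::tibble(
      subject_id = facts$subject_id,
      visit = ifelse(is.na(facts$visit_id), "", facts$visit_id),
      entity = facts$entity,
      variable = variable,
      value_chr = facts$value_chr,
      value_num = facts$value_num,
      value_type = facts$value_type,
      timestamp = facts$timestamp,
      ord = seq_len(n))
  } else {
    cell <- tibble::tibble(subject_id = character(), visit = character(),
                           entity = character(), variable = character(),
                           value_chr = character(), value_num = numeric(),
                           value_type = character(),
                           timestamp = as.POSIXct(character(), tz = "UTC"),
                           ord = integer())
  }

  collapse_one <- function(d) {
    if (nrow(d) == 1) return(d)
    if (policy == "mean" && all(d$value_type == "numeric")) {
      out <- d[1, , drop = FALSE]
      out$value_num <- mean(d$value_num)
      out$value_chr <- format(out$value_num, trim = TRUE, scientific = FALSE)
      return(out)
    }
    if (policy == "first") {
      return(d[order(d$ord)[1], , drop = FALSE])
    }
    # latest: max timestamp; untimed values sort earliest; ties keep-first
    ts <- as.numeric(d$timestamp)
    ts[is.na(ts)] <- -Inf
    d[order(-ts, d$ord)[1], , drop = FALSE]
  }

  grp <- paste(cell$subject_id, cell$visit, cell$variable, sep = KEY_SEP)
  agg_rows <- list()
  if (anyDuplicated(grp)) {
    pieces <- split(cell, grp)
    kept <- lapply(pieces, function(d) {
      if (nrow(d) > 1) {
        agg_rows[[length(agg_rows) + 1L]] <<- tibble::tibble(
          subject_id = d$subject_id[1], visit = d$visit[1],
          variable = d$variable[1], collapsed = nrow(d) - 1L)
      }
      collapse_one(d)
    })
    cell <- dplyr::bind_rows(kept)
    cell <- cell[order(cell$ord), , drop = FALSE]
  }
  aggregation <- structure(list(
    cells = if (length(agg_rows)) dplyr::bind_rows(agg_rows) else
      tibble::tibble(subject_id = character(), visit = character(),
                     variable = character(), collapsed = integer()),
    total_collapsed = n - nrow(cell),
    policy = policy), class = "aggregation_report")

  variables <- sort(unique(cell$variable), method = "radix")
  wide_key <- paste(cell$subject_id, cell$visit, sep = KEY_SEP)
  rows_keys <- unique(tibble::tibble(subject_id = cell$subject_id,
                                     visit = cell$visit,
                                     k = wide_key))
  rows_keys <- rows_keys[order(rows_keys$subject_id, rows_keys$visit,
                               method = "radix"), , drop = FALSE]
  wide <- tibble::tibble(SUBJ_ID = rows_keys$subject_id,
                         VISIT_NAME = rows_keys$visit)
  for (v in variables) {
    sel <- cell$variable == v
    wide[[v]] <- cell$value_chr[sel][match(rows_keys$k, wide_key[sel])]
  }

  entity_of_variable <- cell$entity[match(variables, cell$variable)]
  data_file <- paste0(study, "/clinical/", study, "_clinical_data.tsv")
  files <- list()
  files[[data_file]] <- tsv_text(wide)
  files[[paste0(study, "/clinical/", study, "_column_mapping.tsv")]] <-
    tsv_text(tibble::tibble(
      filename = paste0(study, "_clinical_data.tsv"),
      category_cd = c("", "",
                      paste0(sanitize_id(cfg$study_label), "+",
                             sanitize_id(entity_of_variable))),
      column_number = as.character(seq_len(ncol(wide))),
      data_label = c("SUBJ_ID", "VISIT_NAME", variables)))
  files[[paste0(study, "/clinical/", study, "_word_mapping.tsv")]] <-
    tsv_text(tibble::tibble(filename = character(),
                            column_number = character(),
                            original = character(), mapped = character()))
  invocation <- paste0(
    "backend: tMDataLoader\n",
    "study directory: ", study, "/ (clinical data + mapping files under ",
    study, "/clinical/)\n",
    "aggregation policy for repeated measurements: ", policy, "\n")
  files[[paste0(study, "/invocation.txt")]] <- invocation

  bundle <- new_bundle("transmart-dir", files,
                       counts = list(subjects = nrow(subjects),
                                     facts = nrow(cell),
                                     collapsed = aggregation$total_collapsed),
                       invocation = invocation, aggregation = aggregation)
  list(bundle = bundle, aggregation = aggregation)
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat("<aggregation_report> policy:", x$policy,
      "| values collapsed away:", x$total_collapsed, "\n")
  invisible(x)
}
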