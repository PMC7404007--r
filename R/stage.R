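# End-to-end staging: extraction, transformation, writing — with a
# machine-readable run report.

#' Stage a study end to end
#'
#' Runs the full pipeline: parse the configuration, ingest every bound
#' source (encoding + dialect detection), validate the model against the
#' observed headers, apply declarative filters, expand EAV entities into
#' generated attributes, denormalize into attribute records, build
#' subjects/visits/facts, deduplicate, derive the coded ontology, and
#' compile one staging bundle per requested target dialect. With
#' `out_dir` set, bundles are written under `out_dir/i2b2` and
#' `out_dir/transmart` together with a JSON run report.
#'
#' Validation findings abort the run before anything is written. In
#' `strict` mode any ingest or cleansing anomaly (ragged rows, unparseable
#' timestamps, ...) also aborts.
#'
#' @param config Path to the YAML configuration, or a parsed
#'   `staging_config`.
#' @param data_dir Directory source paths are resolved against (defaults
#'   to the configuration file's directory).
#' @param targets Subset of `c("i2b2", "transmart")`.
#' @param out_dir Output directory; `NULL` keeps bundles in memory only.
#' @param force Overwrite an existing non-empty output directory.
#' @param strict Turn anomalies into errors.
#' @return A `staging_result` with elements `config`, `subjects`,
#'   `visits`, `facts`, `ontology`, `bundles` (named list),
#'   `aggregation`, `dedup`, `report` (run report list), `anomalies`
#'   (tibble).
#' @export
stage_study <- function(config, data_dir = NULL,
                        targets = c("i2b2", "transmart"),
                        out_dir = NULL, force = FALSE, strict = FALSE) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (is.character(config)) {
    data_dir <- data_dir %||% dirname(config)
    cfg <- parse_config(config)
  } else {
    cfg <- config
    data_dir <- data_dir %||% "."
  }
  stopifnot(inherits(cfg, "staging_config"))
  strict <- strict || isTRUE(cfg$options$strict)
  tokens <- cfg$options$missing_tokens
  conventions <- list(day_first = cfg$options$day_first)

  # -- extraction ----------------------------------------------------
  tables <- list()
  rows_read <- list()
  anomalies <- new_anomaly_log()
  for (s in cfg$sources) {
    path <- if (file.exists(s$path)) s$path else file.path(data_dir, s$path)
    tab <- read_table(path, binding = s, strict = strict)
    tables[[s$logical_name]] <- tab
    rows_read[[s$logical_name]] <- nrow(tab)
    anomalies <- dplyr::bind_rows(anomalies, source_ingest_log(tab))
  }

  headers <- lapply(tables, names)
  findings <- validate_config(cfg, headers)
  # filters with numeric predicates must sit on numeric columns
  for (f in cfg$filters) {
    if (f$predicate == "numeric-range" && !is.null(tables[[f$source]]) &&
        f$column %in% names(tables[[f$source]])) {
      prof <- profile_column(
        normalize_missing(tables[[f$source]][[f$column]], tokens)$cells,
        conventions)
      if (prof$inferred_type != "numeric") {
        findings <- dplyr::bind_rows(findings, tibble::tibble(
          scope = "filter", name = paste0(f$source, ".", f$column),
          kind = "type-mismatch",
          message = paste0("numeric-range filter on non-numeric column `",
                           f$column, "` (inferred ", prof$inferred_type,
                           ")")))
      }
    }
  }
  if (nrow(findings) > 0) {
    abort(paste0("configuration is not executable (", nrow(findings),
                 " finding(s)):\n",
                 paste0("  - [", findings$kind, "] ", findings$message,
                        collapse = "\n")),
          class = "clinstage_validation_error")
  }

  # -- transformation ------------------------------------------------
  filter_removed <- list()
  for (nm in names(tables)) {
    fr <- apply_filters(tables[[nm]], cfg$filters, tokens)
    tables[[nm]] <- fr$table
    filter_removed[[nm]] <- fr$rows_removed
  }

  for (e in cfg$entities) {
    if (!is.null(e$eav)) cfg <- expand_eav_entities(cfg, tables[[e$source]])
  }

  records <- list()
  skip_counts <- c(missing_parameter = 0L, missing_value = 0L)
  for (e in cfg$entities) {
    res <- if (!is.null(e$eav)) {
      denormalize_eav(tables[[e$source]], e, cfg)
    } else {
      widen_declared(tables[[e$source]], e, cfg)
    }
    records[[e$name]] <- res$records
    for (k in names(res$skipped)) {
      skip_counts[k] <- sum(skip_counts[k], res$skipped[[k]], na.rm = TRUE)
    }
  }
  records <- dplyr::bind_rows(records)

  roles <- map_chr(cfg$sources, "role")
  patient_tab <- tables[[names(cfg$sources)[roles == "patient-file"]]]
  visit_tab <- if (any(roles == "visit-file")) {
    tables[[names(cfg$sources)[roles == "visit-file"]]]
  }

  sb <- build_subjects(patient_tab, cfg)
  vb <- build_visits(visit_tab, cfg, sb$subjects)
  profiles <- profile_attributes(records, conventions)
  fb <- assemble_facts(records, sb$subjects, vb$visits, profiles, cfg)
  anomalies <- dplyr::bind_rows(anomalies, fb$warnings)
  dd <- deduplicate_facts(fb$facts, cfg$options$duplicate_policy)
  tree <- build_ontology(cfg, profiles)

  if (strict && nrow(anomalies) > 0) {
    abort(paste0("strict mode: ", nrow(anomalies), " anomaly(ies), e.g. ",
                 anomalies$kind[1], " at ", anomalies$source[1], ":",
                 anomalies$row_id[1]),
          class = "clinstage_strict_error")
  }

  # -- writing -------------------------------------------------------
  bundles <- list()
  aggregation <- NULL
  if ("i2b2" %in% targets) {
    bundles$i2b2 <- emit_i2b2_bundle(sb$subjects, vb$visits, dd$facts,
                                     tree, cfg)
  }
  if ("transmart" %in% targets) {
    tm <- emit_transmart_bundle(sb$subjects, dd$facts, tree, cfg)
    bundles$transmart <- tm$bundle
    aggregation <- tm$aggregation
  }

  report <- list(
    version = as.character(utils::packageVersion("clinstage")),
    study = cfg$study_label,
    rows_read = rows_read,
    rows_filtered_out = filter_removed,
    records = nrow(records),
    records_skipped = as.list(skip_counts),
    subjects = nrow(sb$subjects),
    subject_rows_rejected = nrow(sb$rejected),
    subject_conflicts = nrow(sb$conflicts),
    visits = nrow(vb$visits),
    visit_rows_rejected = nrow(vb$rejected),
    facts_assembled = nrow(fb$facts),
    fact_records_rejected = nrow(fb$rejected),
    exact_duplicates_dropped = dd$report$exact_duplicates_dropped,
    value_conflicts = nrow(dd$report$conflicts),
    facts = nrow(dd$facts),
    transmart_values_collapsed = if (!is.null(aggregation))
      aggregation$total_collapsed else NA_integer_,
    ontology_nodes = nrow(tree),
    anomalies = nrow(anomalies),
    targets = targets)

  result <- structure(list(
    config = cfg, subjects = sb$subjects, visits = vb$visits,
    facts = dd$facts, ontology = tree, bundles = bundles,
    aggregation = aggregation, dedup = dd$report,
    rejections = list(subjects = sb$rejected, visits = vb$rejected,
                      facts = fb$rejected),
    conflicts = sb$conflicts,
    report = report, anomalies = anomalies), class = "staging_result")

  if (!is.null(out_dir)) {
    run_params <- list(config = cfg$study_label, targets = targets,
                       strict = strict)
    for (t in names(bundles)) {
      write_bundle(bundles[[t]], file.path(out_dir, t), force = force,
                   run_params = run_params)
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.staging_result <- function(x, ...) {
  r <- x$report
  cat("<staging_result> study:", r$study, "\n")
  cat("  subjects:", r$subjects, "| visits:", r$visits,
      "| facts:", r$facts, "| ontology nodes:", r$ontology_nodes, "\n")
  cat("  duplicates dropped:", r$exact_duplicates_dropped,
      "| conflicts:", r$value_conflicts,
      "| anomalies:", r$anomalies, "\n")
  cat("  bundles:", paste(names(x$bundles), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the counts of a staging run
#'
#' One row per pipeline counter (rows read per source, records, subjects,
#' visits, facts, duplicates, rejections, ...), in pipeline order.
#'
#' @param x A `staging_result`.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @export
tidy.staging_result <- function(x, ...) {
  r <- x$report
  rows <- tibble::tibble(
    metric = paste0("rows_read.", names(r$rows_read)),
    value = as.numeric(unlist(r$rows_read)))
  scalars <- c("records", "subjects", "visits", "facts_assembled",
               "exact_duplicates_dropped", "value_conflicts", "facts",
               "ontology_nodes", "anomalies")
  dplyr::bind_rows(rows, tibble::tibble(
    metric = scalars,
    value = as.numeric(unlist(r[scalars]))))
}

#' One-row summary of a staging run
#'
#' @inheritParams tidy.staging_result
#' @return A one-row tibble: `study`, `subjects`, `visits`, `facts`,
#'   `ontology_nodes`, `duplicates_dropped`, `anomalies`, `targets`.
#' @export
glance.staging_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    study = r$study, subjects = r$subjects, visits = r$visits,
    facts = r$facts, ontology_nodes = r$ontology_nodes,
    duplicates_dropped = r$exact_duplicates_dropped,
    anomalies = r$anomalies,
    targets = paste(r$targets, collapse = "+"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the pipeline counters of a staging run
#'
#' A horizontal bar chart of the run-report counters, in pipeline order —
#' a quick visual check of where rows were lost (filters, missing values,
#' duplicates) between raw input and emitted facts.
#'
#' @param object A `staging_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staging_result <- function(object, ...) {
  d <- tidy.staging_result(object)
  d$metric <- factor(d$metric, levels = rev(d$metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$value), hjust = -0.15,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .12))) +
    ggplot2::labs(x = "count", y = NULL,
                  title = paste("Staging run:", object$report$study)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
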