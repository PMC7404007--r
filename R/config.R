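#' Parse a declarative staging configuration
#'
#' Reads the YAML document that maps an entity-relationship model onto a set
#' of delimited input files. The document has four top-level sections:
#' `study` (a label), `sources` (named file bindings with roles
#' `patient-file`, `visit-file` or `data-file`), `entities` (each anchored to
#' a patient or visit, carrying declared attributes and/or an EAV
#' specification), and optional `filters` and `options`.
#'
#' All defaults are filled in: missing-value tokens default to
#' `"", "NA", "N/A", "NULL", "-", "."`; the duplicate policy defaults to
#' `keep-first`; ambiguous numeric dates are read day-first; the tranSMART
#' repeated-measurement aggregation policy defaults to `latest`. Unknown keys
#' anywhere in the document are rejected, so typos fail loudly rather than
#' being silently ignored.
#'
#' @param document Path to a YAML file, or a single string containing YAML.
#' @return A `staging_config` object (a structured list).
#' @export
#' @examples
#' cfg <- parse_config(example_config_text())
#' cfg$study_label
parse_config <- function(document) {
  is_path <- length(document) == 1 && !grepl("\n", document) &&
    file.exists(document)
  if (!is_path && length(document) == 1 &&
      grepl("\\.ya?ml$", document) && !file.exists(document)) {
    abort(paste0("configuration file not found: ", document),
          class = "clinstage_io_error")
  }
  raw <- tryCatch(
    if (is_path) yaml::read_yaml(document) else yaml::yaml.load(document),
    error = function(e) {
      abort(paste0("configuration is not well-formed YAML: ",
                   conditionMessage(e)), class = "clinstage_parse_error")
    }
  )
  if (!is.list(raw)) {
    abort("configuration must be a YAML mapping", class = "clinstage_parse_error")
  }
  assert_known_keys(raw, c("study", "sources", "entities", "filters", "options"),
                    "top level")
  if (is.null(raw$study) || !nzchar(as.character(raw$study)[1])) {
    abort("configuration must name a study (`study:`)",
          class = "clinstage_schema_error")
  }
  if (is.null(raw$sources) || length(raw$sources) == 0) {
    abort("configuration must declare at least one source",
          class = "clinstage_schema_error")
  }
  if (is.null(raw$entities) || length(raw$entities) == 0) {
    abort("configuration must declare at least one entity",
          class = "clinstage_schema_error")
  }

  sources <- imap(raw$sources, parse_source_binding)
  entities <- map(raw$entities, parse_entity_def)

  nm <- tolower(map_chr(entities, "name"))
  if (anyDuplicated(nm)) {
    dup <- unique(map_chr(entities, "name")[duplicated(nm)])
    abort(paste0("duplicate entity name(s): ", paste(dup, collapse = ", ")),
          class = "clinstage_schema_error")
  }

  roles <- map_chr(sources, "role")
  if (sum(roles == "patient-file") != 1) {
    abort("exactly one source must have role patient-file",
          class = "clinstage_schema_error")
  }
  if (sum(roles == "visit-file") > 1) {
    abort("at most one source may have role visit-file",
          class = "clinstage_schema_error")
  }

  filters <- map(raw$filters %||% list(), parse_filter_spec)
  options <- parse_options(raw$options %||% list())

  patient <- sources[[which(roles == "patient-file")]]
  visit <- if (any(roles == "visit-file")) sources[[which(roles == "visit-file")]]

  cfg <- structure(list(
    study_label = as.character(raw$study)[1],
    sources = sources,
    entities = entities,
    subject_key = patient$key_columns,
    visit_key = if (!is.null(visit)) visit$key_columns,
    filters = filters,
    options = options
  ), class = "staging_config")
  validate_config_shape(cfg)
  cfg
}

assert_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(paste0("unknown key(s) at ", where, ": ",
                 paste(extra, collapse = ", ")),
          class = "clinstage_schema_error")
  }
}

parse_source_binding <- function(spec, logical_name) {
  assert_known_keys(spec, c("path", "role", "key_columns", "visit_key_columns",
                            "timestamp_column", "end_timestamp_column"),
                    paste0("source `", logical_name, "`"))
  role <- spec$role %||% "data-file"
  if (!role %in% c("patient-file", "visit-file", "data-file")) {
    abort(paste0("source `", logical_name, "`: unknown role `", role, "`"),
          class = "clinstage_schema_error")
  }
  key_columns <- as.character(spec$key_columns %||% character())
  if (role %in% c("patient-file", "visit-file") && length(key_columns) == 0) {
    abort(paste0("source `", logical_name, "` (", role,
                 ") must declare key_columns"),
          class = "clinstage_schema_error")
  }
  list(
    logical_name = logical_name,
    path = spec$path %||% logical_name,
    role = role,
    key_columns = key_columns,
    visit_key_columns = as.character(spec$visit_key_columns %||% character()),
    timestamp_column = spec$timestamp_column,
    end_timestamp_column = spec$end_timestamp_column
  )
}

parse_entity_def <- function(spec) {
  assert_known_keys(spec, c("name", "anchor", "source", "attributes", "eav"),
                    paste0("entity `", spec$name %||% "?", "`"))
  if (is.null(spec$name) || is.null(spec$source)) {
    abort("every entity needs `name` and `source`",
          class = "clinstage_schema_error")
  }
  anchor <- spec$anchor %||% "patient"
  if (!anchor %in% c("patient", "visit", "encounter")) {
    abort(paste0("entity `", spec$name, "`: unknown anchor `", anchor, "`"),
          class = "clinstage_schema_error")
  }
  attributes <- map(spec$attributes %||% list(), parse_attribute_def,
                    entity = spec$name)
  eav <- if (!is.null(spec$eav)) parse_eav_spec(spec$eav, spec$name)
  if (length(attributes) == 0 && is.null(eav)) {
    abort(paste0("entity `", spec$name,
                 "` must declare attributes or an eav block"),
          class = "clinstage_schema_error")
  }
  anm <- map_chr(attributes, "name")
  if (anyDuplicated(anm)) {
    abort(paste0("entity `", spec$name, "`: duplicate attribute name(s): ",
                 paste(unique(anm[duplicated(anm)]), collapse = ", ")),
          class = "clinstage_schema_error")
  }
  list(name = spec$name, anchor = anchor, source = spec$source,
       attributes = attributes, eav = eav)
}

parse_attribute_def <- function(spec, entity) {
  assert_known_keys(spec, c("name", "column", "type", "meta", "generated"),
                    paste0("attribute in entity `", entity, "`"))
  if (is.null(spec$name) || is.null(spec$column)) {
    abort(paste0("entity `", entity,
                 "`: every attribute needs `name` and `column`"),
          class = "clinstage_schema_error")
  }
  type <- spec$type %||% "auto"
  if (!type %in% c("auto", "numeric", "categorical", "date", "text")) {
    abort(paste0("attribute `", spec$name, "`: unknown type `", type, "`"),
          class = "clinstage_schema_error")
  }
  meta <- map(spec$meta %||% list(), parse_meta_def, owner = spec$name)
  mnm <- map_chr(meta, "name")
  if (anyDuplicated(mnm)) {
    abort(paste0("attribute `", spec$name, "`: duplicate meta-attribute names"),
          class = "clinstage_schema_error")
  }
  list(name = spec$name, column = spec$column, declared_type = type,
       meta = meta, generated = isTRUE(spec$generated))
}

parse_meta_def <- function(spec, owner) {
  assert_known_keys(spec, c("name", "column"),
                    paste0("meta-attribute of `", owner, "`"))
  if (is.null(spec$name) || is.null(spec$column)) {
    abort(paste0("meta-attribute of `", owner,
                 "` needs `name` and `column`"),
          class = "clinstage_schema_error")
  }
  list(name = spec$name, column = spec$column)
}

parse_eav_spec <- function(spec, entity) {
  assert_known_keys(spec, c("parameter_columns", "value_column",
                            "meta_columns", "label_join"),
                    paste0("eav block of entity `", entity, "`"))
  pc <- as.character(spec$parameter_columns %||% character())
  if (length(pc) < 1) {
    abort(paste0("entity `", entity,
                 "`: eav block needs at least one parameter column"),
          class = "clinstage_schema_error")
  }
  if (is.null(spec$value_column)) {
    abort(paste0("entity `", entity, "`: eav block needs a value_column"),
          class = "clinstage_schema_error")
  }
  if (spec$value_column %in% pc) {
    abort(paste0("entity `", entity,
                 "`: value_column must not be a parameter column"),
          class = "clinstage_schema_error")
  }
  meta <- map(spec$meta_columns %||% list(), parse_meta_def, owner = entity)
  if (any(map_chr(meta, "column") %in% pc)) {
    abort(paste0("entity `", entity,
                 "`: parameter columns and meta columns must be disjoint"),
          class = "clinstage_schema_error")
  }
  list(parameter_columns = pc, value_column = spec$value_column,
       meta_columns = meta, label_join = spec$label_join %||% "|")
}

parse_filter_spec <- function(spec) {
  assert_known_keys(spec, c("source", "column", "predicate", "values",
                            "min", "max", "action"), "filter")
  pred <- spec$predicate %||% "non-missing"
  if (!pred %in% c("equals", "in-set", "numeric-range", "non-missing")) {
    abort(paste0("unknown filter predicate `", pred, "`"),
          class = "clinstage_schema_error")
  }
  action <- spec$action %||% "keep"
  if (!action %in% c("keep", "drop")) {
    abort(paste0("unknown filter action `", action, "`"),
          class = "clinstage_schema_error")
  }
  list(source = spec$source, column = spec$column, predicate = pred,
       values = as.character(spec$values %||% character()),
       min = spec$min, max = spec$max, action = action)
}

default_missing_tokens <- function() c("", "NA", "N/A", "NULL", "-", ".")

parse_options <- function(spec) {
  assert_known_keys(spec, c("missing_tokens", "duplicate_policy", "day_first",
                            "date_formats", "strict", "transmart_aggregation",
                            "study_code"), "options")
  dup <- spec$duplicate_policy %||% "keep-first"
  if (!dup %in% c("keep-first", "keep-all-conflicts")) {
    abort(paste0("unknown duplicate_policy `", dup, "`"),
          class = "clinstage_schema_error")
  }
  agg <- spec$transmart_aggregation %||% "latest"
  if (!agg %in% c("latest", "first", "mean")) {
    abort(paste0("unknown transmart_aggregation `", agg, "`"),
          class = "clinstage_schema_error")
  }
  list(
    missing_tokens = as.character(spec$missing_tokens %||%
                                    default_missing_tokens()),
    duplicate_policy = dup,
    day_first = spec$day_first %||% TRUE,
    date_formats = as.character(spec$date_formats %||% character()),
    strict = isTRUE(spec$strict),
    transmart_aggregation = agg,
    study_code = spec$study_code %||% NULL
  )
}

validate_config_shape <- function(cfg) {
  src_names <- names(cfg$sources)
  for (e in cfg$entities) {
    if (!e$source %in% src_names) {
      abort(paste0("entity `", e$name, "` references unknown source `",
                   e$source, "`"), class = "clinstage_schema_error")
    }
  }
  for (f in cfg$filters) {
    if (!is.null(f$source) && !f$source %in% src_names) {
      abort(paste0("filter references unknown source `", f$source, "`"),
            class = "clinstage_schema_error")
    }
  }
  invisible(cfg)
}

#' @export
print.staging_config <- function(x, ...) {
  cat("<staging_config> study:", x$study_label, "\n")
  cat("  sources: ", paste0(names(x$sources), " (",
                            map_chr(x$sources, "role"), ")",
                            collapse = ", "), "\n", sep = "")
  for (e in x$entities) {
    cat("  entity ", e$name, " [", e$anchor, " <- ", e$source, "]: ",
        length(e$attributes), " attribute(s)",
        if (!is.null(e$eav)) paste0(", EAV on ",
                                    paste(e$eav$parameter_columns,
                                          collapse = "+")),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a staging configuration back to YAML
#'
#' Inverse of [parse_config()]: `parse_config(serialize_config(cfg))`
#' reproduces `cfg`. Generated (EAV-expanded) attributes are not serialized;
#' they are derived state, re-created from data on every run.
#'
#' @param cfg A `staging_config`.
#' @return A single YAML string.
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "staging_config"))
  ser_meta <- function(m) map(m, function(x) list(name = x$name, column = x$column))
  doc <- list(
    study = cfg$study_label,
    sources = map(cfg$sources, function(s) {
      out <- list(path = s$path, role = s$role)
      if (length(s$key_columns)) out$key_columns <- as.list(s$key_columns)
      if (length(s$visit_key_columns))
        out$visit_key_columns <- as.list(s$visit_key_columns)
      if (!is.null(s$timestamp_column)) out$timestamp_column <- s$timestamp_column
      if (!is.null(s$end_timestamp_column))
        out$end_timestamp_column <- s$end_timestamp_column
      out
    }),
    entities = map(cfg$entities, function(e) {
      out <- list(name = e$name, anchor = e$anchor, source = e$source)
      decl <- keep(e$attributes, ~ !.x$generated)
      if (length(decl)) {
        out$attributes <- map(decl, function(a) {
          al <- list(name = a$name, column = a$column)
          if (a$declared_type != "auto") al$type <- a$declared_type
          if (length(a$meta)) al$meta <- ser_meta(a$meta)
          al
        })
      }
      if (!is.null(e$eav)) {
        ev <- list(parameter_columns = as.list(e$eav$parameter_columns),
                   value_column = e$eav$value_column)
        if (length(e$eav$meta_columns))
          ev$meta_columns <- ser_meta(e$eav$meta_columns)
        if (!identical(e$eav$label_join, "|")) ev$label_join <- e$eav$label_join
        out$eav <- ev
      }
      out
    })
  )
  if (length(cfg$filters)) {
    doc$filters <- map(cfg$filters, function(f) {
      out <- list(source = f$source, column = f$column, predicate = f$predicate)
      if (length(f$values)) out$values <- as.list(f$values)
      if (!is.null(f$min)) out$min <- f$min
      if (!is.null(f$max)) out$max <- f$max
      out$action <- f$action
      out
    })
  }
  o <- cfg$options
  opt <- list()
  if (!identical(o$missing_tokens, default_missing_tokens()))
    opt$missing_tokens <- as.list(o$missing_tokens)
  if (!identical(o$duplicate_policy, "keep-first"))
    opt$duplicate_policy <- o$duplicate_policy
  if (!isTRUE(o$day_first)) opt$day_first <- o$day_first
  if (length(o$date_formats)) opt$date_formats <- as.list(o$date_formats)
  if (isTRUE(o$strict)) opt$strict <- TRUE
  if (!identical(o$transmart_aggregation, "latest"))
    opt$transmart_aggregation <- o$transmart_aggregation
  if (!is.null(o$study_code)) opt$study_code <- o$study_code
  if (length(opt)) doc$options <- opt
  yaml::as.yaml(doc)
}

#' Validate a configuration against actual source headers
#'
#' Checks every column reference (attribute columns, meta-attribute columns,
#' EAV parameter/value/meta columns, key and timestamp columns, filter
#' columns) against the headers observed in the ingested sources, plus the
#' structural assumptions the pipeline makes (a patient file must exist;
#' visit-anchored entities need a way to resolve visits). Validation never
#' raises: it returns a tibble of findings, one row per problem. An empty
#' tibble means the configuration is executable.
#'
#' @param cfg A `staging_config`.
#' @param headers Named list mapping each logical source name to its character
#'   vector of column names.
#' @return A tibble with columns `scope`, `name`, `kind`, `message`.
#' @export
validate_config <- function(cfg, headers) {
  stopifnot(inherits(cfg, "staging_config"))
  findings <- list()
  add <- function(scope, name, kind, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      scope = scope, name = name, kind = kind, message = message)
  }
  col_ok <- function(src, col) {
    !is.null(headers[[src]]) && col %in% headers[[src]]
  }

  roles <- map_chr(cfg$sources, "role")
  if (!any(roles == "patient-file")) {
    add("config", cfg$study_label, "missing-patient-file",
        "no source has role patient-file; one file must describe the patients or probands")
  }

  for (s in cfg$sources) {
    if (is.null(headers[[s$logical_name]])) {
      add("source", s$logical_name, "unresolved-source",
          paste0("no headers available for source `", s$logical_name, "`"))
      next
    }
    for (col in c(s$key_columns, s$visit_key_columns)) {
      if (!col_ok(s$logical_name, col)) {
        add("source", s$logical_name, "unresolved-column",
            paste0("key column `", col, "` not found in source `",
                   s$logical_name, "`"))
      }
    }
    for (col in compact(list(s$timestamp_column, s$end_timestamp_column))) {
      if (!col_ok(s$logical_name, col)) {
        add("source", s$logical_name, "unresolved-column",
            paste0("timestamp column `", col, "` not found in source `",
                   s$logical_name, "`"))
      }
    }
  }

  has_visit_file <- any(roles == "visit-file")
  for (e in cfg$entities) {
    src <- e$source
    if (is.null(headers[[src]])) next  # already reported
    for (a in e$attributes) {
      if (!col_ok(src, a$column)) {
        add("attribute", paste0(e$name, ".", a$name), "unresolved-column",
            paste0("column `", a$column, "` not found in source `", src, "`"))
      }
      for (m in a$meta) {
        if (!col_ok(src, m$column)) {
          add("meta-attribute", paste0(e$name, ".", a$name, ".", m$name),
              "unresolved-column",
              paste0("column `", m$column, "` not found in source `", src, "`"))
        }
      }
    }
    if (!is.null(e$eav)) {
      for (col in c(e$eav$parameter_columns, e$eav$value_column)) {
        if (!col_ok(src, col)) {
          add("entity", e$name, "unresolved-column",
              paste0("EAV column `", col, "` not found in source `", src, "`"))
        }
      }
      for (m in e$eav$meta_columns) {
        if (!col_ok(src, m$column)) {
          add("meta-attribute", paste0(e$name, ".", m$name),
              "unresolved-column",
              paste0("column `", m$column, "` not found in source `", src, "`"))
        }
      }
    }
    if (e$anchor %in% c("visit", "encounter")) {
      binding <- cfg$sources[[src]]
      if (!has_visit_file && length(binding$visit_key_columns) == 0 &&
          is.null(binding$timestamp_column)) {
        add("entity", e$name, "unresolvable-visit-anchor",
            paste0("entity `", e$name, "` is visit-anchored but there is no ",
                   "visit file, no visit key columns and no timestamp column"))
      }
    }
  }

  for (f in cfg$filters) {
    if (!is.null(headers[[f$source]]) && !col_ok(f$source, f$column)) {
      add("filter", paste0(f$source, ".", f$column), "unresolved-column",
          paste0("filter column `", f$column, "` not found in source `",
                 f$source, "`"))
    }
  }

  if (length(findings) == 0) {
    tibble::tibble(scope = character(), name = character(),
                   kind = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

# Normalize a parameter label before distinctness comparison: trim outer
# whitespace and collapse internal runs; comparison stays case-sensitive so
# clinically distinct codes are never merged silently.
normalize_parameter_label <- function(x) {
  str_squish(x)
}

#' Expand EAV specifications into generated attributes
#'
#' Scans an EAV-shaped source table and, for each entity whose EAV block is
#' bound to it, adds one generated attribute per distinct observed
#' parameter-value combination (multiple parameter columns are combined with
#' the entity's `label_join` separator, `"|"` by default). Labels are
#' whitespace-normalized (outer trim, inner runs collapsed) before
#' distinctness is decided; comparison is case-sensitive. Each generated
#' attribute inherits the EAV block's meta-attribute columns. Rows with an
#' empty parameter cell are excluded from expansion and counted in the
#' attached expansion log. Expansion is idempotent and order-independent:
#' generated attributes are re-derived from scratch and sorted by name.
#'
#' A generated name colliding with a declared attribute name is an error —
#' a silent overwrite would corrupt the ontology.
#'
#' @param cfg A `staging_config`.
#' @param table A `source_table` (see [read_table()]).
#' @return The expanded `staging_config`; its `expansion_log` field is a
#'   tibble of per-entity row-exclusion counts.
#' @export
expand_eav_entities <- function(cfg, table) {
  stopifnot(inherits(cfg, "staging_config"), inherits(table, "source_table"))
  tokens <- cfg$options$missing_tokens
  log <- cfg$expansion_log %||%
    tibble::tibble(entity = character(), source = character(),
                   distinct_parameters = integer(), rows_skipped = integer())
  lname <- attr(table, "logical_name")

  cfg$entities <- map(cfg$entities, function(e) {
    if (is.null(e$eav) || !identical(e$source, lname)) return(e)
    # re-derivation from scratch keeps expansion idempotent
    e$attributes <- keep(e$attributes, ~ !.x$generated)

    pc <- e$eav$parameter_columns
    cells <- map(pc, function(col) {
      normalize_missing(normalize_parameter_label(table[[col]]), tokens)$cells
    })
    ok <- Reduce(`&`, map(cells, ~ !is.na(.x)))
    skipped <- sum(!ok)
    combos <- if (any(ok)) {
      unique(do.call(paste, c(map(cells, ~ .x[ok]), sep = e$eav$label_join)))
    } else character()
    combos <- sort(combos, method = "radix")

    declared <- map_chr(e$attributes, "name")
    clash <- intersect(combos, declared)
    if (length(clash)) {
      abort(paste0("entity `", e$name, "`: EAV-generated attribute name(s) ",
                   "collide with declared attributes: ",
                   paste(clash, collapse = ", ")),
            class = "clinstage_schema_error")
    }
    generated <- map(combos, function(label) {
      list(name = label, column = e$eav$value_column, declared_type = "auto",
           meta = e$eav$meta_columns, generated = TRUE)
    })
    e$attributes <- c(e$attributes, generated)
    log <<- dplyr::bind_rows(log, tibble::tibble(
      entity = e$name, source = lname,
      distinct_parameters = length(combos), rows_skipped = skipped))
    e
  })
  cfg$expansion_log <- log
  cfg
}

#' A minimal example configuration
#'
#' Returns YAML text for a two-source study (a patient file plus an EAV lab
#' file) used throughout the documentation.
#'
#' @return A YAML string accepted by [parse_config()].
#' @export
example_config_text <- function() {
  paste(
    "study: DEMO",
    "sources:",
    "  patients:",
    "    path: patients.csv",
    "    role: patient-file",
    "    key_columns: [PatientID]",
    "  labs:",
    "    path: labs.csv",
    "    role: data-file",
    "    key_columns: [PatientID]",
    "    timestamp_column: Date",
    "entities:",
    "  - name: Demographics",
    "    anchor: patient",
    "    source: patients",
    "    attributes:",
    "      - {name: Sex, column: Sex}",
    "      - {name: YearOfBirth, column: YearOfBirth, type: numeric}",
    "  - name: Laboratory",
    "    anchor: patient",
    "    source: labs",
    "    eav:",
    "      parameter_columns: [Parameter]",
    "      value_column: Result",
    "      meta_columns:",
    "        - {name: Unit, column: Unit}",
    "        - {name: Norm range, column: NormRange}",
    sep = "\n")
}
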