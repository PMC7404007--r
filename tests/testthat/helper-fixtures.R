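# Shared fixtures: tiny configs, in-memory tables, an independent
# brute-force EAV pivot oracle, and a minimal two-file study writer.

minimal_config_text <- function() {
  paste(
    "study: MINI",
    "sources:",
    "  patients:",
    "    path: patients.csv",
    "    role: patient-file",
    "    key_columns: [PatientID]",
    "entities:",
    "  - name: Demographics",
    "    anchor: patient",
    "    source: patients",
    "    attributes:",
    "      - {name: Sex, column: Sex}",
    sep = "\n")
}

fig4_config_text <- function() {
  paste(
    "study: LABSTUDY",
    "sources:",
    "  patients:",
    "    path: patients.csv",
    "    role: patient-file",
    "    key_columns: [PatientID]",
    "  labdata:",
    "    path: labdata.csv",
    "    role: data-file",
    "    key_columns: [PatientID]",
    "entities:",
    "  - name: Patient",
    "    anchor: patient",
    "    source: patients",
    "    attributes:",
    "      - {name: Sex, column: Sex}",
    "  - name: LabValues",
    "    anchor: patient",
    "    source: labdata",
    "    eav:",
    "      parameter_columns: [Parameter]",
    "      value_column: Result",
    "      meta_columns:",
    "        - {name: Unit, column: Unit}",
    "        - {name: Norm range, column: \"Norm range\"}",
    sep = "\n")
}

# EAV table shaped like a lab export: Parameter/Result/Unit/Norm range.
fig4_table <- function() {
  as_source_table(data.frame(
    PatientID = c("P1", "P1"),
    Parameter = c("LDL", "CRP"),
    Result = c("140", "0.5"),
    Unit = c("mg/dL", "mg/L"),
    `Norm range` = c("<130", ""),
    check.names = FALSE), "labdata")
}

# Tiny key/visit/timestamp model shared by the fact-builder and emitter
# tests: patients by PID, visits by (PID, VID) with start/end, an EAV lab
# file timed by Date.
facts_fixture_cfg <- function() {
  parse_config(paste(
    "study: FX",
    "sources:",
    "  patients:",
    "    path: patients.csv",
    "    role: patient-file",
    "    key_columns: [PID]",
    "  visits:",
    "    path: visits.csv",
    "    role: visit-file",
    "    key_columns: [PID, VID]",
    "    timestamp_column: Start",
    "    end_timestamp_column: End",
    "  labs:",
    "    path: labs.csv",
    "    role: data-file",
    "    key_columns: [PID]",
    "    timestamp_column: Date",
    "entities:",
    "  - name: Demo",
    "    anchor: patient",
    "    source: patients",
    "    attributes: [{name: Sex, column: Sex}]",
    "  - name: Lab",
    "    anchor: visit",
    "    source: labs",
    "    eav:",
    "      parameter_columns: [Par]",
    "      value_column: Val",
    sep = "\n"))
}

# Independent brute-force pivot oracle for EAV denormalization: explicit
# per-row loops, no shared code with the implementation.
eav_pivot_oracle <- function(df, param_cols, value_col, meta_defs,
                             sep = "|",
                             tokens = c("", "NA", "N/A", "NULL", "-", ".")) {
  is_miss <- function(x) is.na(x) || tolower(trimws(x)) %in% tolower(tokens)
  squish <- function(s) gsub("[[:space:]]+", " ", trimws(s))
  recs <- character()
  skip_param <- 0L
  skip_value <- 0L
  for (i in seq_len(nrow(df))) {
    pv <- vapply(param_cols, function(cc) df[[cc]][i], character(1))
    if (any(vapply(pv, is_miss, logical(1)))) {
      skip_param <- skip_param + 1L
      next
    }
    v <- df[[value_col]][i]
    if (is_miss(v)) {
      skip_value <- skip_value + 1L
      next
    }
    meta_bits <- character()
    for (m in meta_defs) {
      cell <- df[[m$column]][i]
      if (!is_miss(cell)) meta_bits <- c(meta_bits,
                                         paste0(m$name, "=", cell))
    }
    meta_bits <- sort(meta_bits, method = "radix")
    recs <- c(recs, paste(paste(vapply(pv, squish, character(1)),
                                collapse = sep),
                          v, paste(meta_bits, collapse = ";"), i,
                          sep = "\x1f"))
  }
  list(records = sort(recs, method = "radix"),
       skip_param = skip_param, skip_value = skip_value)
}

# Canonical comparable form of denormalize_eav() output, mirroring the
# oracle's record encoding (row index relative to data rows).
records_as_strings <- function(records, row_offset = 1L) {
  if (nrow(records) == 0) return(character())
  out <- vapply(seq_len(nrow(records)), function(i) {
    m <- records$meta[[i]]
    bits <- if (length(m)) sort(paste0(names(m), "=", m),
                                method = "radix") else character()
    paste(records$attribute[i], records$value[i],
          paste(bits, collapse = ";"),
          records$row_id[i] - row_offset, sep = "\x1f")
  }, character(1))
  sort(out, method = "radix")
}

# Random EAV table for property tests (values/parameters drawn under the
# caller's seed).
random_eav_df <- function(n_rows, n_params, n_param_cols) {
  pool1 <- paste0("PAR", seq_len(n_params))
  pool2 <- c("Serum", "Urine", "Plasma")
  df <- data.frame(
    PatientID = paste0("P", sample(1:4, n_rows, replace = TRUE)),
    Parameter = sample(c(pool1, NA), n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
  if (n_param_cols == 2) {
    df$Material <- sample(c(pool2, ""), n_rows, replace = TRUE)
  }
  df$Result <- ifelse(runif(n_rows) < 0.15, "",
                      as.character(round(runif(n_rows, 1, 200), 1)))
  df$Unit <- sample(c("mg/dL", "mmol/L", ""), n_rows, replace = TRUE)
  df[is.na(df)] <- "NA"
  df
}

eav_cfg_for <- function(param_cols) {
  txt <- paste(
    "study: RND",
    "sources:",
    "  patients:",
    "    path: p.csv",
    "    role: patient-file",
    "    key_columns: [PatientID]",
    "  tab:",
    "    path: t.csv",
    "    role: data-file",
    "    key_columns: [PatientID]",
    "entities:",
    "  - name: P",
    "    anchor: patient",
    "    source: patients",
    "    attributes:",
    "      - {name: X, column: PatientID}",
    "  - name: E",
    "    anchor: patient",
    "    source: tab",
    "    eav:",
    paste0("      parameter_columns: [",
           paste(param_cols, collapse = ", "), "]"),
    "      value_column: Result",
    "      meta_columns:",
    "        - {name: Unit, column: Unit}",
    sep = "\n")
  parse_config(txt)
}

# Two-file study with declared attributes only (no meta-attributes, no
# repeated measurements): the fixture on which both dialects must agree.
write_mini_study <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("PatientID,Sex,Age",
               "P1,m,44", "P2,f,61", "P3,f,29"),
             file.path(dir, "patients.csv"))
  writeLines(c("PatientID,Score,Grade",
               "P1,12.5,A", "P2,7,B", "P3,9.5,A"),
             file.path(dir, "obs.csv"))
  cfg_text <- paste(
    "study: MINI",
    "sources:",
    "  patients:",
    "    path: patients.csv",
    "    role: patient-file",
    "    key_columns: [PatientID]",
    "  obs:",
    "    path: obs.csv",
    "    role: data-file",
    "    key_columns: [PatientID]",
    "entities:",
    "  - name: Demographics",
    "    anchor: patient",
    "    source: patients",
    "    attributes:",
    "      - {name: Sex, column: Sex}",
    "      - {name: Age, column: Age}",
    "  - name: Assessment",
    "    anchor: patient",
    "    source: obs",
    "    attributes:",
    "      - {name: Score, column: Score}",
    "      - {name: Grade, column: Grade}",
    sep = "\n")
  writeLines(cfg_text, file.path(dir, "study.yaml"))
  file.path(dir, "study.yaml")
}

# Melt a written tranSMART clinical data file back into per-fact rows.
melt_transmart <- function(bundle_dir) {
  study_dirs <- list.dirs(bundle_dir, recursive = FALSE)
  clin <- list.files(file.path(study_dirs[1], "clinical"),
                     pattern = "_clinical_data\\.tsv$", full.names = TRUE)
  lines <- readLines(clin, encoding = "UTF-8")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  out <- list()
  for (ln in lines[-1]) {
    cells <- strsplit(paste0(ln, "\x1e"), "\t", fixed = TRUE)[[1]]
    cells[length(cells)] <- sub("\x1e$", "", cells[length(cells)])
    for (j in seq(3, length(header))) {
      if (j <= length(cells) && nzchar(cells[j])) {
        out[[length(out) + 1L]] <- data.frame(
          subject_id = cells[1], visit = cells[2],
          variable = header[j], value = cells[j])
      }
    }
  }
  do.call(rbind, out)
}
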