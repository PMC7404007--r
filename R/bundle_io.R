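# Writing staging bundles to disk and reading the i2b2 dialect back.

#' Write a staging bundle to disk
#'
#' Files are first written into a temporary sibling directory, then moved
#' into place with a single rename, so a crashed run never leaves a
#' half-written bundle. An existing non-empty output directory is refused
#' unless `force = TRUE`. A `manifest.json` with per-file checksums, model
#' counts and run parameters is written alongside the bundle files.
#'
#' @param bundle A `staging_bundle`.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @param run_params Optional named list recorded in the manifest.
#' @return Path of the written manifest (invisibly).
#' @export
write_bundle <- function(bundle, out_dir, force = FALSE, run_params = list()) {
  stopifnot(inherits(bundle, "staging_bundle"))
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = TRUE,
                                        no.. = TRUE)) > 0) {
    if (!force) {
      abort(paste0("output directory exists and is not empty: ", out_dir,
                   " (use force to overwrite)"),
            class = "clinstage_io_error")
    }
    unlink(out_dir, recursive = TRUE)
  }
  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("bundle_", tmpdir = parent)
  dir.create(tmp, recursive = TRUE)

  for (rel in names(bundle$files)) {
    dest <- file.path(tmp, rel)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    con <- file(dest, open = "wb")
    writeBin(charToRaw(enc2utf8(bundle$files[[rel]])), con)
    close(con)
  }
  manifest <- bundle$manifest
  manifest$run_params <- run_params
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(tmp, out_dir)) {
    # rename can fail across filesystems; fall back to copy
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(dir(tmp, full.names = TRUE), out_dir, recursive = TRUE)
    unlink(tmp, recursive = TRUE)
  }
  invisible(file.path(out_dir, "manifest.json"))
}

read_tsv_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1) {
    return(tibble::as_tibble(setNames(
      rep(list(character()), length(header)), header)))
  }
  parts <- stringi::stri_split_fixed(lines[-1], "\t")
  cells <- matrix("", nrow = length(parts), ncol = length(header))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    cells[i, seq_len(min(length(p), length(header)))] <-
      p[seq_len(min(length(p), length(header)))]
  }
  tibble::as_tibble(setNames(
    lapply(seq_along(header), function(j) cells[, j]), header))
}

#' Read an i2b2 staging bundle back into a fact table
#'
#' Independent reader over the written file set: reconstructs the fact
#' multiset (subject, visit, concept path, typed value, timestamp token,
#' modifier map) by re-grouping the long observation rows on their
#' instance numbers, and reads subjects, visits and the ontology file.
#' Used to verify that staging is lossless in the i2b2 dialect.
#'
#' @param dir Directory a bundle was written to with [write_bundle()].
#' @return A list: `facts`, `subjects`, `visits`, `ontology` tibbles.
#' @export
read_i2b2_bundle <- function(dir) {
  subj <- read_tsv_file(file.path(dir, "subjects.tsv"))
  visits <- if (file.exists(file.path(dir, "visits.tsv"))) {
    read_tsv_file(file.path(dir, "visits.tsv"))
  } else {
    tibble::tibble(visit_id = character(), subject_id = character())
  }
  ontology <- read_tsv_file(file.path(dir, "ontology.tsv"))

  fact_files <- dir(dir, pattern = "^facts_.*\\.tsv$", full.names = TRUE)
  facts <- list()
  for (ff in sort(fact_files)) {
    long <- read_tsv_file(ff)
    if (nrow(long) == 0) next
    long$.file <- basename(ff)
    grp <- paste(long$.file, long$instance_num, sep = "\x1f")
    value_rows <- long[long$modifier_cd == "@", , drop = FALSE]
    vgrp <- grp[long$modifier_cd == "@"]
    mod_rows <- long[long$modifier_cd != "@", , drop = FALSE]
    mgrp <- grp[long$modifier_cd != "@"]
    mod_name <- character(nrow(mod_rows))
    if (nrow(mod_rows) > 0) {
      code_to_name <- setNames(ontology$name, ontology$code)
      mod_name <- unname(code_to_name[mod_rows$modifier_cd])
    }
    meta <- lapply(vgrp, function(g) {
      sel <- which(mgrp == g)
      if (length(sel) == 0) return(character())
      setNames(mod_rows$value[sel], mod_name[sel])
    })
    facts[[length(facts) + 1L]] <- tibble::tibble(
      subject_id = value_rows$subject_id,
      visit_id = ifelse(value_rows$visit_id == "", NA_character_,
                        value_rows$visit_id),
      concept_path = value_rows$concept_path,
      value_type = value_rows$value_type,
      value = value_rows$value,
      timestamp = value_rows$timestamp,
      ts_precision = value_rows$ts_precision,
      meta = meta)
  }
  facts <- if (length(facts)) dplyr::bind_rows(facts) else
    tibble::tibble(subject_id = character(), visit_id = character(),
                   concept_path = character(), value_type = character(),
                   value = character(), timestamp = character(),
                   ts_precision = character(), meta = list())
  list(facts = facts, subjects = subj, visits = visits, ontology = ontology)
}

# Canonical multiset representation of a fact table (either the in-model
# tibble or the re-read bundle form) for exact comparisons.
fact_multiset <- function(facts) {
  if ("value_chr" %in% names(facts)) {
    value <- facts$value_chr
    ts <- fmt_ts(facts$timestamp, facts$ts_precision)
  } else {
    value <- facts$value
    ts <- ifelse(is.na(facts$timestamp), "", facts$timestamp)
  }
  key <- paste(facts$subject_id,
               ifelse(is.na(facts$visit_id), "", facts$visit_id),
               facts$concept_path, value, ts,
               meta_signature(facts$meta), sep = "\x1f")
  sort(key, method = "radix")
}
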