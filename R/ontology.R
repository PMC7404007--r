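# Prefix-closed concept hierarchy with stable codes, derived from the
# expanded ER model.

#' Build the concept ontology from an expanded configuration
#'
#' Lays concepts out as `\study\entity\attribute\`, with one folder node
#' per study and entity, one concept node per (declared or EAV-generated)
#' attribute, and one modifier node per meta-attribute beneath its concept.
#' Path segments are sanitized (backslash, slash and control characters
#' become `_`; 200-character cap); a collision created by sanitization is
#' an error naming the colliding sources — a silent merge would conflate
#' distinct concepts. Nodes are ordered lexicographically by path, so the
#' tree is byte-identical across runs. Folder nodes carry value type
#' `none`; concept value types come from the attribute profiles.
#'
#' @param cfg An expanded `staging_config` (after [expand_eav_entities()]).
#' @param profiles Attribute profiles (named `entity\x1fattribute`), as
#'   produced inside [stage_study()]; `NULL` gives every concept type
#'   `text`.
#' @return An `ontology` tibble: `full_path`, `name`, `level`, `kind`,
#'   `value_type`, `code`.
#' @export
build_ontology <- function(cfg, profiles = NULL) {
  stopifnot(inherits(cfg, "staging_config"))
  study_seg <- sanitize_segment(cfg$study_label)
  rows <- list(tibble::tibble(
    full_path = paste0("\\", study_seg, "\\"), name = cfg$study_label,
    level = 1L, kind = "folder", value_type = "none", origin = "study"))

  for (e in cfg$entities) {
    ent_seg <- sanitize_segment(e$name)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      full_path = paste0("\\", study_seg, "\\", ent_seg, "\\"),
      name = e$name, level = 2L, kind = "folder", value_type = "none",
      origin = paste0("entity:", e$name))
    for (a in e$attributes) {
      p <- profiles[[paste(e$name, a$name, sep = KEY_SEP)]]
      vt <- if (a$declared_type != "auto") a$declared_type
            else if (!is.null(p)) p$inferred_type else "text"
      apath <- paste0("\\", study_seg, "\\", ent_seg, "\\",
                      sanitize_segment(a$name), "\\")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        full_path = apath, name = a$name, level = 3L, kind = "concept",
        value_type = vt, origin = paste0("attribute:", e$name, ".", a$name))
      for (m in a$meta) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          full_path = paste0(apath, sanitize_segment(m$name), "\\"),
          name = m$name, level = 4L, kind = "modifier", value_type = "text",
          origin = paste0("meta:", e$name, ".", a$name, ".", m$name))
      }
    }
  }
  tree <- dplyr::bind_rows(rows)

  dup <- tree$full_path[duplicated(tree$full_path)]
  if (length(dup)) {
    origins <- tree$origin[tree$full_path %in% dup]
    abort(paste0("ontology path collision after sanitization: ",
                 paste(unique(dup), collapse = ", "), " (from ",
                 paste(origins, collapse = "; "), ")"),
          class = "clinstage_ontology_error")
  }
  tree <- tree[order(tree$full_path, method = "radix"), , drop = FALSE]
  tree$origin <- NULL
  tree <- assign_codes(tree)
  structure(tree, class = c("ontology", class(tibble::tibble())))
}

#' Assign stable codes to ontology nodes
#'
#' Each node's code is the first 16 hexadecimal characters of a
#' deterministic 128-bit digest of its full path, so codes are identical
#' across runs and machines without any database sequence, and a node's
#' code never changes when unrelated nodes are added. In the (astronomically
#' unlikely) event of a truncated-digest collision the full digest is used
#' for the colliding nodes.
#'
#' @param tree An ontology tibble (with `full_path`).
#' @return The tree with a `code` column; codes are injective.
#' @export
assign_codes <- function(tree) {
  code <- path_code(tree$full_path)
  if (anyDuplicated(code)) {
    clash <- code %in% code[duplicated(code)]
    code[clash] <- vapply(tree$full_path[clash], rlang::hash, character(1))
    warn("ontology code collision at 16 hex chars; full digest used")
  }
  tree$code <- unname(code)
  tree
}

# Every ancestor of every node must itself be a node.
ontology_is_prefix_closed <- function(tree) {
  paths <- tree$full_path
  for (p in paths) {
    segs <- strsplit(sub("^\\\\", "", sub("\\\\$", "", p)), "\\\\")[[1]]
    if (length(segs) <= 1) next
    for (k in seq_len(length(segs) - 1)) {
      anc <- paste0("\\", paste(segs[seq_len(k)], collapse = "\\"), "\\")
      if (!anc %in% paths) return(FALSE)
    }
  }
  TRUE
}
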