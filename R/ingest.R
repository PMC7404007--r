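# Robust ingestion of delimited text files: encoding detection, dialect
# sniffing, quote-aware parsing into an all-character tibble.

DIALECT_CANDIDATES <- c(",", ";", "\t", "|")
SNIFF_LINES <- 100L

#' Detect the character encoding of raw file bytes
#'
#' A byte-order mark, when present, takes absolute precedence (UTF-8,
#' UTF-16LE, UTF-16BE). Otherwise a statistical detector proposes candidate
#' encodings; candidates that fail to decode the bytes are discarded, and
#' ties are broken by the fixed priority UTF-8 > ISO-8859-1 > UTF-16 so that
#' repeated runs make identical decisions. Valid UTF-8 input is always
#' reported as UTF-8 regardless of detector opinion: UTF-8 false positives
#' on real text are vanishingly rare, while single-byte codepages decode
#' anything.
#'
#' @param raw A raw vector (file contents).
#' @return A list with elements `encoding` (label usable with
#'   [stringi::stri_encode()]) and `confidence` in `[0, 1]`.
#' @export
detect_encoding <- function(raw) {
  stopifnot(is.raw(raw), length(raw) > 0)
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
    return(list(encoding = "UTF-8", confidence = 1, bom = TRUE))
  }
  if (length(raw) >= 2 && identical(raw[1:2], as.raw(c(0xFF, 0xFE)))) {
    return(list(encoding = "UTF-16LE", confidence = 1, bom = TRUE))
  }
  if (length(raw) >= 2 && identical(raw[1:2], as.raw(c(0xFE, 0xFF)))) {
    return(list(encoding = "UTF-16BE", confidence = 1, bom = TRUE))
  }

  if (stringi::stri_enc_isascii(raw)) {
    return(list(encoding = "UTF-8", confidence = 1, bom = FALSE))
  }
  if (stringi::stri_enc_isutf8(raw)) {
    return(list(encoding = "UTF-8", confidence = 0.99, bom = FALSE))
  }

  guesses <- stringi::stri_enc_detect(raw)[[1]]
  priority <- c("UTF-8", "ISO-8859-1", "UTF-16LE", "UTF-16BE")
  decodes <- function(enc) {
    out <- tryCatch(
      suppressWarnings(iconv(list(raw), from = enc, to = "UTF-8")),
      error = function(e) NA_character_)
    length(out) == 1 && !is.na(out)
  }
  viable <- guesses[vapply(guesses$Encoding, decodes, logical(1)), ,
                    drop = FALSE]
  if (nrow(viable) > 0) {
    best <- viable$Confidence == max(viable$Confidence)
    cand <- viable$Encoding[best]
    pr <- match(cand, priority)
    pick <- cand[order(ifelse(is.na(pr), length(priority) + 1L, pr))][1]
    return(list(encoding = pick,
                confidence = max(viable$Confidence), bom = FALSE))
  }
  # last resort: ISO-8859-1 maps every byte; only unreachable in theory
  if (decodes("ISO-8859-1")) {
    return(list(encoding = "ISO-8859-1", confidence = 0.1, bom = FALSE))
  }
  bad <- which(vapply(seq_along(raw), function(i) {
    is.na(suppressWarnings(iconv(list(raw[seq_len(i)]), "ISO-8859-1",
                                 "UTF-8")))
  }, logical(1)))[1]
  abort(paste0("no candidate encoding decodes the input; first undecodable ",
               "byte at offset ", bad), class = "clinstage_encoding_error")
}

count_fields_per_line <- function(lines, delimiter, quote_char = "\"") {
  vapply(lines, function(ln) {
    n <- tryCatch(
      length(split_delimited_line(ln, delimiter, quote_char)),
      error = function(e) NA_integer_)
    as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
}

# Quote-aware field splitting for one line. Lines without the quote
# character take the vectorizable fast path.
split_delimited_line <- function(line, delimiter, quote_char = "\"") {
  if (!grepl(quote_char, line, fixed = TRUE)) {
    return(stringi::stri_split_fixed(line, delimiter)[[1]])
  }
  out <- scan(text = line, what = character(), sep = delimiter,
              quote = quote_char, quiet = TRUE, na.strings = character(),
              strip.white = FALSE, blank.lines.skip = FALSE)
  out
}

#' Sniff the delimiter dialect of decoded text
#'
#' Evaluates the candidate delimiters comma, semicolon, tab and pipe on up
#' to `max_lines` lines, scoring each by column-count consistency (the
#' fraction of lines showing the modal field count, zeroed when the modal
#' count is 1 or quoting is unbalanced). The winner is the highest-scoring
#' candidate; ties fall back to the fixed candidate order for
#' reproducibility. A header line is inferred from type contrast: some
#' column whose later rows parse as numbers while the first row's cell does
#' not. When no candidate yields more than one column the table is treated
#' as single-column with delimiter `","` and a warning is logged.
#'
#' @param sample Decoded text (single string or character vector of lines).
#' @param max_lines Number of lines to inspect (default 100).
#' @return A `dialect` list: `delimiter`, `quote_char`, `has_header`,
#'   `line_terminator`, plus `fallback` flag.
#' @export
detect_dialect <- function(sample, max_lines = SNIFF_LINES) {
  if (length(sample) == 1) {
    terminator <- if (grepl("\r\n", sample, fixed = TRUE)) "\r\n" else "\n"
    lines <- stringi::stri_split_lines(sample)[[1]]
  } else {
    terminator <- "\n"
    lines <- sample
  }
  lines <- lines[nzchar(lines)]
  stopifnot(length(lines) >= 1)
  lines <- head(lines, max_lines)

  scores <- vapply(DIALECT_CANDIDATES, function(d) {
    counts <- count_fields_per_line(lines, d)
    if (anyNA(counts)) return(0)
    modal <- as.integer(names(which.max(table(counts))))
    if (modal <= 1L) return(0)
    mean(counts == modal)
  }, numeric(1))

  if (all(scores == 0)) {
    return(structure(list(delimiter = ",", quote_char = "\"",
                          has_header = TRUE, line_terminator = terminator,
                          fallback = TRUE), class = "dialect"))
  }
  delim <- DIALECT_CANDIDATES[which.max(scores)]

  has_header <- TRUE
  if (length(lines) >= 2) {
    first <- split_delimited_line(lines[[1]], delim)
    rest <- lapply(lines[-1], split_delimited_line, delimiter = delim)
    ncol <- length(first)
    numericish <- function(x) {
      x <- str_trim(x)
      nzchar(x) & !is.na(suppressWarnings(as.numeric(gsub(",", ".", x))))
    }
    contrast <- FALSE
    for (j in seq_len(ncol)) {
      col <- vapply(rest, function(r) if (length(r) >= j) r[[j]] else "",
                    character(1))
      body_num <- numericish(col)
      if (any(nzchar(str_trim(col))) && all(body_num[nzchar(str_trim(col))]) &&
          !numericish(first[[j]])) {
        contrast <- TRUE
        break
      }
    }
    # no contrasting column and a fully numeric first row: likely headerless
    if (!contrast && all(numericish(first))) has_header <- FALSE
  }

  structure(list(delimiter = delim, quote_char = "\"",
                 has_header = has_header, line_terminator = terminator,
                 fallback = FALSE), class = "dialect")
}

#' Read a delimited file into a source table
#'
#' Detects encoding and dialect, then parses the full file into a tibble of
#' character columns (one per header). Cells are kept verbatim apart from
#' outer-whitespace trimming; missing-value normalization and typing happen
#' later in the pipeline. Ragged rows are repaired per policy — short rows
#' padded with empty cells, long rows truncated — and every repair is logged
#' with the original line number; `strict = TRUE` turns repairs into errors.
#' Fully empty lines are skipped and logged.
#'
#' @param path Path to the delimited text file.
#' @param binding Source binding (from a `staging_config`); a bare logical
#'   name is also accepted.
#' @param strict Abort on ragged rows instead of repairing them.
#' @return A `source_table`: a tibble of character columns with attributes
#'   `logical_name`, `provenance` (path, encoding, dialect), `row_ids`
#'   (original 1-based line numbers) and `ingest_log` (anomaly tibble).
#' @export
read_table <- function(path, binding = NULL, strict = FALSE) {
  if (is.character(binding)) binding <- list(logical_name = binding)
  logical_name <- binding$logical_name %||%
    tools::file_path_sans_ext(basename(path))
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "clinstage_io_error")
  }
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) == 0) {
    abort(paste0("input file is empty: ", path), class = "clinstage_io_error")
  }
  enc <- detect_encoding(raw)
  text <- iconv(list(raw), from = enc$encoding, to = "UTF-8")
  if (is.na(text)) {
    abort(paste0("file does not decode as ", enc$encoding, ": ", path),
          class = "clinstage_encoding_error")
  }
  text <- sub("^\ufeff", "", text)

  dialect <- detect_dialect(text)
  all_lines <- stringi::stri_split_lines(text)[[1]]
  if (length(all_lines) && !nzchar(all_lines[length(all_lines)])) {
    all_lines <- all_lines[-length(all_lines)]
  }

  log <- new_anomaly_log()
  keep_mask <- nzchar(str_trim(all_lines))
  for (i in which(!keep_mask)) {
    log <- log_anomaly(log, "ingest", logical_name, i, "empty-line",
                       "line contains no data; skipped")
  }
  line_nos <- which(keep_mask)
  lines <- all_lines[keep_mask]
  if (length(lines) == 0) {
    abort(paste0("file contains no data lines: ", path),
          class = "clinstage_io_error")
  }

  parsed <- lapply(lines, split_delimited_line,
                   delimiter = dialect$delimiter,
                   quote_char = dialect$quote_char)

  if (dialect$has_header) {
    header <- str_trim(parsed[[1]])
    parsed <- parsed[-1]
    line_nos <- line_nos[-1]
  } else {
    header <- paste0("V", seq_along(parsed[[1]]))
  }
  if (anyDuplicated(header)) {
    abort(paste0("duplicated header name(s) in ", path, ": ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")),
          class = "clinstage_io_error")
  }
  ncol <- length(header)

  widths <- lengths(parsed)
  if (any(widths != ncol)) {
    if (strict) {
      bad <- line_nos[widths != ncol]
      abort(paste0("ragged row(s) at line(s) ",
                   paste(head(bad, 10), collapse = ", "), " in ", path),
            class = "clinstage_ragged_error")
    }
    for (i in which(widths < ncol)) {
      log <- log_anomaly(log, "ingest", logical_name, line_nos[i],
                         "padded-row",
                         paste0("row had ", widths[i], " of ", ncol,
                                " fields; padded with empty cells"))
      parsed[[i]] <- c(parsed[[i]], rep("", ncol - widths[i]))
    }
    for (i in which(widths > ncol)) {
      log <- log_anomaly(log, "ingest", logical_name, line_nos[i],
                         "truncated-row",
                         paste0("row had ", widths[i], " of ", ncol,
                                " fields; extra fields dropped"))
      parsed[[i]] <- parsed[[i]][seq_len(ncol)]
    }
  }

  cells <- if (length(parsed)) {
    matrix(str_trim(unlist(parsed, use.names = FALSE)),
           ncol = ncol, byrow = TRUE)
  } else {
    matrix(character(), ncol = ncol)
  }
  df <- tibble::as_tibble(setNames(
    lapply(seq_len(ncol), function(j) cells[, j]), header))

  new_source_table(df, logical_name = logical_name,
                   provenance = list(path = path, encoding = enc$encoding,
                                     bom = isTRUE(enc$bom), dialect = dialect),
                   row_ids = as.integer(line_nos), ingest_log = log)
}

new_source_table <- function(df, logical_name, provenance = NULL,
                             row_ids = NULL, ingest_log = NULL) {
  structure(
    df,
    logical_name = logical_name,
    provenance = provenance %||% list(path = NA_character_,
                                      encoding = "UTF-8", dialect = NULL),
    row_ids = row_ids %||% (seq_len(nrow(df)) + 1L),
    ingest_log = ingest_log %||% new_anomaly_log(),
    class = c("source_table", class(tibble::as_tibble(df)))
  )
}

#' Build a source table from an in-memory data frame
#'
#' Convenience constructor mirroring the result of [read_table()] for tables
#' that never lived on disk (tests, simulation). All columns are coerced to
#' character.
#'
#' @param df A data frame.
#' @param logical_name Logical source name.
#' @return A `source_table`.
#' @export
as_source_table <- function(df, logical_name) {
  df <- tibble::as_tibble(df)
  df[] <- lapply(df, as.character)
  new_source_table(df, logical_name = logical_name)
}

#' @export
print.source_table <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("<source_table> ", attr(x, "logical_name"), ": ", nrow(x), " row(s) x ",
      ncol(x), " column(s)", sep = "")
  if (!is.null(p$dialect)) {
    cat(" [", p$encoding, ", sep='",
        gsub("\t", "\\\\t", p$dialect$delimiter), "']", sep = "")
  }
  cat("\n")
  print(tibble::as_tibble(unclass_source_table(x)), ...)
  invisible(x)
}

unclass_source_table <- function(x) {
  class(x) <- setdiff(class(x), "source_table")
  x
}

source_row_ids <- function(x) attr(x, "row_ids")
source_logical_name <- function(x) attr(x, "logical_name")
source_ingest_log <- function(x) attr(x, "ingest_log")
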