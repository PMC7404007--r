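test_that("byte-order marks and ASCII resolve deterministically", {
  bom <- c(as.raw(c(0xEF, 0xBB, 0xBF)), charToRaw("a,b\n1,2\n"))
  e <- detect_encoding(bom)
  expect_equal(e$encoding, "UTF-8")
  expect_equal(e$confidence, 1)
  expect_true(e$bom)

  ascii <- charToRaw("a,b\n1,2\n")
  expect_equal(detect_encoding(ascii)$encoding, "UTF-8")

  utf16 <- c(as.raw(c(0xFF, 0xFE)),
             iconv("a;b\n", "UTF-8", "UTF-16LE", toRaw = TRUE)[[1]])
  expect_equal(detect_encoding(utf16)$encoding, "UTF-16LE")
})

test_that("a latin-1 fixture with German text is recovered losslessly", {
  text <- "Name;Größe\nMüller;172\nSchäfer;165\n"
  raw <- iconv(text, "UTF-8", "ISO-8859-1", toRaw = TRUE)[[1]]
  e <- detect_encoding(raw)
  decoded <- iconv(list(raw), from = e$encoding, to = "UTF-8")
  expect_identical(decoded, text)
})

test_that("delimiter sniffing picks the consistent candidate", {
  d1 <- detect_dialect("a;b;c\n1;2;3\n")
  expect_equal(d1$delimiter, ";")
  expect_true(d1$has_header)

  d2 <- detect_dialect("a,b\n\"x,y\",2\n\"p,q\",4\n")
  expect_equal(d2$delimiter, ",")
  expect_equal(d2$quote_char, "\"")

  # exhaustive scoring oracle over the same sample: ',' must be the only
  # candidate giving a constant column count > 1
  sample_lines <- c("a,b", "\"x,y\",2", "\"p,q\",4")
  for (cand in c(";", "\t", "|")) {
    counts <- vapply(sample_lines, function(ln)
      length(clinstage:::split_delimited_line(ln, cand)), integer(1))
    expect_true(length(unique(counts)) > 1 || unique(counts) == 1)
  }

  d3 <- detect_dialect("justonecolumn\nvalue1\nvalue2\n")
  expect_equal(d3$delimiter, ",")
  expect_true(d3$fallback)
})

test_that("header detection uses type contrast with the body", {
  with_header <- detect_dialect("id,age\nA,44\nB,61\n")
  expect_true(with_header$has_header)
  headerless <- detect_dialect("1,44\n2,61\n3,29\n")
  expect_false(headerless$has_header)
})

test_that("read_table parses shape, row ids and provenance", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3", "4,5,6"), p)
  tab <- read_table(p, "t")
  expect_equal(names(tab), c("a", "b", "c"))
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "row_ids"), c(2L, 3L))
  expect_equal(attr(tab, "provenance")$encoding, "UTF-8")

  pd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,a", "1,2,3"), pd)
  expect_error(read_table(pd, "t"), "a", class = "clinstage_io_error")
})

test_that("ragged rows are repaired and logged, or rejected when strict", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2", "4,5,6,7", "7,8,9"), p)
  tab <- read_table(p, "t")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$c[1], "")           # padded
  expect_equal(unlist(tab[2, ]), c(a = "4", b = "5", c = "6"))  # truncated
  log <- attr(tab, "ingest_log")
  expect_setequal(log$kind, c("padded-row", "truncated-row"))
  expect_equal(log$row_id, c(2L, 3L))
  expect_error(read_table(p, "t", strict = TRUE),
               class = "clinstage_ragged_error")
})

test_that("parsed content is invariant under encoding x delimiter", {
  df <- data.frame(PatientID = c("P1", "P2"),
                   City = c("München", "Straßberg"),
                   Value = c("1.5", "2.25"))
  ref <- NULL
  for (enc in c("UTF-8", "UTF-8-BOM", "ISO-8859-1")) {
    for (delim in c(",", ";", "\t", "|")) {
      d <- withr::local_tempdir()
      f <- file.path(d, "t.csv")
      clinstage:::write_delim_file(df, f, delimiter = delim, encoding = enc)
      tab <- read_table(f, "t")
      content <- as.data.frame(lapply(tab, c), stringsAsFactors = FALSE)
      if (is.null(ref)) ref <- content else expect_identical(content, ref)
    }
  }
})

test_that("identical bytes give identical source tables", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "x,1", "y,2"), p)
  t1 <- read_table(p, "t")
  t2 <- read_table(p, "t")
  expect_identical(t1, t2)
})
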