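test_that("missing tokens normalize case-insensitively after trimming", {
  r <- normalize_missing(c("1", "NA", "", "2"))
  expect_equal(r$missing_count, 2)
  expect_equal(r$cells, c("1", NA, NA, "2"))

  expect_true(is.na(normalize_missing("na")$cells))
  expect_true(is.na(normalize_missing(" N/a ")$cells))

  r0 <- normalize_missing(character())
  expect_equal(r0$cells, character())
  expect_equal(r0$missing_count, 0)

  # custom token set
  rc <- normalize_missing(c("missing", "NA"), tokens = "missing")
  expect_equal(rc$cells, c(NA, "NA"))
})

test_that("type inference follows the all-or-nothing numeric rule", {
  p1 <- profile_column(c("1.5", "2", "3"))
  expect_equal(p1$inferred_type, "numeric")
  expect_equal(p1$decimal_separator, ".")
  expect_equal(p1$numeric_parse_fraction, 1)

  # decimal comma only without dots and digits-comma-digits throughout
  p2 <- profile_column(c("1,5", "2,0", "17"))
  expect_equal(p2$inferred_type, "numeric")
  expect_equal(p2$decimal_separator, ",")

  # one stray cell demotes the whole column
  p3 <- profile_column(c("1.5", "abc", "2"))
  expect_false(p3$inferred_type == "numeric")
  expect_equal(p3$inferred_type, "categorical")
  expect_lt(p3$numeric_parse_fraction, 1)

  # mixed dot and comma cells are never numeric-comma
  p4 <- profile_column(c("1,5", "2.5"))
  expect_false(p4$inferred_type == "numeric")

  p5 <- profile_column(c("2019-01-02", "2020-03-04", "2021-05-06"))
  expect_equal(p5$inferred_type, "date")

  many <- as.character(seq_len(500) + 0.5)
  many[1] <- "x"  # not numeric, high cardinality
  expect_equal(profile_column(many)$inferred_type, "text")

  expect_equal(profile_column(c(NA, NA))$missing_count, 2)
})

test_that("column profiles are permutation-invariant", {
  cells <- c("1.5", "x", "1.5", NA, "7", "y")
  p <- profile_column(cells)
  withr::with_seed(5, {
    for (i in 1:10) {
      q <- profile_column(sample(cells))
      expect_equal(q, p)
    }
  })
})

test_that("timestamps parse with the precision present in the token", {
  t1 <- parse_timestamp("2019")
  expect_equal(t1$precision, "year")
  expect_equal(format(t1$instant, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               "2019-01-01 00:00:00")

  t2 <- parse_timestamp("2019-03")
  expect_equal(t2$precision, "month")
  expect_equal(format(t2$instant, "%Y-%m-%d", tz = "UTC"), "2019-03-01")

  t3 <- parse_timestamp("02.03.2019")
  expect_equal(t3$precision, "day")
  expect_equal(format(t3$instant, "%Y-%m-%d", tz = "UTC"), "2019-03-02")

  t4 <- parse_timestamp("02.03.2019", list(day_first = FALSE))
  expect_equal(format(t4$instant, "%Y-%m-%d", tz = "UTC"), "2019-02-03")

  t5 <- parse_timestamp("2019-03-02T14:30")
  expect_equal(t5$precision, "minute")

  expect_error(parse_timestamp("not a date"),
               class = "clinstage_timestamp_error")
  expect_error(parse_timestamp("2019-02-30"),
               class = "clinstage_timestamp_error")
})

test_that("re-rendering an instant at its precision reproduces the token", {
  tokens <- c("2019", "2019-03", "2019-03-02", "2019-03-02 14:30",
              "2019-03-02 14:30:59")
  for (tok in tokens) {
    t <- parse_timestamp(tok)
    expect_equal(clinstage:::format_timestamp(t$instant, t$precision), tok)
  }
})

test_that("filters keep and drop rows as declared", {
  df <- data.frame(Status = c(rep("final", 4), rep("draft", 6)),
                   Value = as.character(1:10))
  tab <- as_source_table(df, "src")
  keep_final <- list(list(source = "src", column = "Status",
                          predicate = "in-set", values = "final",
                          min = NULL, max = NULL, action = "keep"))
  r <- apply_filters(tab, keep_final)
  expect_equal(nrow(r$table), 4)
  expect_equal(r$rows_removed, 6)
  expect_equal(r$per_filter$removed, 6L)

  r0 <- apply_filters(tab, list())
  expect_equal(nrow(r0$table), 10)
  expect_equal(r0$rows_removed, 0)

  rng <- list(list(source = "src", column = "Value",
                   predicate = "numeric-range", values = character(),
                   min = 3, max = 7, action = "keep"))
  expect_equal(nrow(apply_filters(tab, rng)$table), 5)

  drop_draft <- list(list(source = "src", column = "Status",
                          predicate = "equals", values = "draft",
                          min = NULL, max = NULL, action = "drop"))
  expect_equal(nrow(apply_filters(tab, drop_draft)$table), 4)
})

test_that("filters on disjoint columns commute", {
  withr::with_seed(21, {
    df <- data.frame(A = sample(c("x", "y"), 30, TRUE),
                     B = as.character(sample(1:5, 30, TRUE)))
    tab <- as_source_table(df, "src")
    fA <- list(source = "src", column = "A", predicate = "equals",
               values = "x", min = NULL, max = NULL, action = "keep")
    fB <- list(source = "src", column = "B", predicate = "numeric-range",
               values = character(), min = 2, max = 4, action = "keep")
    r1 <- apply_filters(tab, list(fA, fB))
    r2 <- apply_filters(tab, list(fB, fA))
    expect_identical(as.data.frame(r1$table), as.data.frame(r2$table))
    expect_equal(r1$rows_removed, nrow(tab) - nrow(r1$table))
  })
})
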