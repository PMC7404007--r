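test_that("subjects merge duplicate keys and log demographic conflicts", {
  cfg <- facts_fixture_cfg()
  tab <- as_source_table(data.frame(
    PID = c("P1", "P2", "P3", "P4", "P5"),
    Sex = c("m", "f", "f", "m", "f"),
    Birth = c("1960", "1971", "1980", "1955", "1999")), "patients")
  sb <- build_subjects(tab, cfg)
  expect_equal(nrow(sb$subjects), 5)
  expect_equal(sb$subjects$subject_id[1], "FX_P1")

  dup <- as_source_table(data.frame(
    PID = c("P1", "P1"), Sex = c("m", "m"), Birth = c("1960", "1960")),
    "patients")
  sb2 <- build_subjects(dup, cfg)
  expect_equal(nrow(sb2$subjects), 1)
  expect_equal(nrow(sb2$conflicts), 0)

  conf <- as_source_table(data.frame(
    PID = c("P1", "P1"), Sex = c("m", "m"), Birth = c("1960", "1961")),
    "patients")
  sb3 <- build_subjects(conf, cfg)
  expect_equal(nrow(sb3$subjects), 1)
  expect_equal(sb3$subjects$Birth, "1960")  # keep-first
  expect_equal(nrow(sb3$conflicts), 1)
  expect_equal(sb3$conflicts$discarded, "1961")

  missing_key <- as_source_table(data.frame(
    PID = c("P1", ""), Sex = c("m", "f"), Birth = c("1960", "1970")),
    "patients")
  sb4 <- build_subjects(missing_key, cfg)
  expect_equal(nrow(sb4$subjects), 1)
  expect_equal(sb4$rejected$reason, "missing-subject-key")
})

test_that("visits link to subjects; inconsistent or orphan rows rejected", {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = c("P1", "P2", "P3"), Sex = "m"), "patients"), cfg)$subjects
  vt <- as_source_table(data.frame(
    PID = c("P1", "P2", "P3", "P1", "P9"),
    VID = c("V1", "V1", "V1", "V2", "V1"),
    Start = c("2020-01-05", "2020-02-01", "2020-03-01",
              "2020-06-01", "2020-01-01"),
    End = c("2020-01-10", "2020-02-03", "2020-02-20",  # P3: end < start
            "2020-06-02", "2020-01-02")), "visits")
  vb <- build_visits(vt, cfg, subs)
  expect_equal(nrow(vb$visits), 3)
  expect_setequal(vb$rejected$reason,
                  c("inconsistent-timestamp-end-before-start",
                    "orphan-visit-unknown-subject"))

  none <- build_visits(NULL, cfg, subs)
  expect_equal(nrow(none$visits), 0)
})

test_that("facts link to visits by key or unambiguous timestamp window", {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = c("P1", "P2"), Sex = "m"), "patients"), cfg)$subjects
  visits <- build_visits(as_source_table(data.frame(
    PID = c("P1", "P1", "P2"), VID = c("V1", "V2", "V1"),
    Start = c("2020-01-01", "2020-02-01", "2020-01-01"),
    End = c("2020-01-10", "2020-02-10", "2020-01-10")), "visits"),
    cfg, subs)$visits

  tab <- as_source_table(data.frame(
    PID = c("P1", "P1", "P1", "P9"),
    Par = "LDL",
    Val = c("140", "150", "160", "170"),
    Date = c("2020-01-05",     # inside V1 only -> linked
             "2020-03-15",     # inside no window -> unlinked
             "2019-12-31",     # outside all windows
             "2020-01-05")),   # unknown subject -> rejected
    "labs")
  recs <- denormalize_eav(tab, cfg$entities[[2]], cfg)$records
  fb <- assemble_facts(recs, subs, visits, cfg = cfg)
  expect_equal(nrow(fb$facts), 3)
  expect_equal(fb$facts$visit_id[1], visits$visit_id[1])
  expect_true(all(is.na(fb$facts$visit_id[2:3])))
  expect_equal(fb$rejected$reason, "unknown-subject-key")

  # oracle: exhaustive interval check agrees on every fact
  for (i in seq_len(nrow(fb$facts))) {
    t <- fb$facts$timestamp[i]
    cand <- sum(visits$subject_id == fb$facts$subject_id[i] &
                  visits$start <= t & t <= visits$end)
    if (cand == 1) expect_false(is.na(fb$facts$visit_id[i]))
    else expect_true(is.na(fb$facts$visit_id[i]))
  }
})

test_that("a timestamp covered by two windows is never guessed", {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = "P1", Sex = "m"), "patients"), cfg)$subjects
  visits <- build_visits(as_source_table(data.frame(
    PID = c("P1", "P1"), VID = c("V1", "V2"),
    Start = c("2020-01-01", "2020-01-05"),
    End = c("2020-01-10", "2020-01-15")), "visits"), cfg, subs)$visits
  tab <- as_source_table(data.frame(
    PID = "P1", Par = "CRP", Val = "2", Date = "2020-01-07"), "labs")
  recs <- denormalize_eav(tab, cfg$entities[[2]], cfg)$records
  fb <- assemble_facts(recs, subs, visits, cfg = cfg)
  expect_true(is.na(fb$facts$visit_id))
  expect_true("ambiguous-visit-linkage" %in% fb$warnings$kind)
})

test_that("numeric values are typed and decimal-normalized", {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = "P1", Sex = "m"), "patients"), cfg)$subjects
  tab <- as_source_table(data.frame(
    PID = c("P1", "P1"), Par = c("LDL", "LDL"),
    Val = c("140,5", "99,25"), Date = c("", "")), "labs")
  recs <- denormalize_eav(tab, cfg$entities[[2]], cfg)$records
  fb <- assemble_facts(recs, subs, build_visits(NULL, cfg, subs)$visits,
                       cfg = cfg)
  expect_equal(fb$facts$value_type, c("numeric", "numeric"))
  expect_equal(fb$facts$value_chr, c("140.5", "99.25"))
  expect_equal(fb$facts$value_num, c(140.5, 99.25))
})

make_dup_facts <- function() {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = paste0("P", 1:5), Sex = "m"), "patients"), cfg)$subjects
  tab <- as_source_table(data.frame(
    PID = paste0("P", 1:5), Par = "LDL",
    Val = as.character(100 + 1:5), Date = "2020-01-01"), "labs")
  recs <- denormalize_eav(tab, cfg$entities[[2]], cfg)$records
  assemble_facts(recs, subs, build_visits(NULL, cfg, subs)$visits,
                 cfg = cfg)$facts
}

test_that("exact duplicates collapse; value conflicts resolve keep-first", {
  facts <- make_dup_facts()
  for (k in c(1, 3)) {
    injected <- dplyr::bind_rows(facts, facts[rep(1, k), ])
    dd <- deduplicate_facts(injected)
    expect_equal(nrow(dd$facts), nrow(facts))
    expect_equal(dd$report$exact_duplicates_dropped, k)
  }

  clean <- deduplicate_facts(facts)
  expect_equal(nrow(clean$facts), nrow(facts))
  expect_equal(clean$report$exact_duplicates_dropped, 0)
  expect_equal(nrow(clean$report$conflicts), 0)

  conflicted <- dplyr::bind_rows(facts,
                                 dplyr::mutate(facts[1, ],
                                               value_chr = "999",
                                               value_num = 999))
  dd2 <- deduplicate_facts(conflicted)
  expect_equal(nrow(dd2$facts), nrow(facts))
  expect_equal(dd2$facts$value_chr[1], facts$value_chr[1])
  expect_equal(nrow(dd2$report$conflicts), 1)
  expect_equal(dd2$report$conflicts$discarded, "999")
})

test_that("deduplication is idempotent and conserves counts", {
  facts <- make_dup_facts()
  injected <- dplyr::bind_rows(facts, facts[c(1, 1, 2), ])
  once <- deduplicate_facts(injected)
  twice <- deduplicate_facts(once$facts)
  expect_identical(twice$facts, once$facts)
  expect_equal(twice$report$exact_duplicates_dropped, 0)
  # conservation: in == out + dropped + conflicts resolved away
  expect_equal(nrow(injected),
               nrow(once$facts) + once$report$exact_duplicates_dropped +
                 nrow(once$report$conflicts))
})

test_that("facts differing only in modifiers are not duplicates", {
  facts <- make_dup_facts()
  variant <- facts[1, ]
  variant$meta <- list(c(Unit = "mmol/L"))
  variant$meta_sig <- clinstage:::meta_signature(variant$meta)
  dd <- deduplicate_facts(dplyr::bind_rows(facts, variant))
  expect_equal(nrow(dd$facts), nrow(facts) + 1)
  expect_equal(dd$report$exact_duplicates_dropped, 0)
})
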