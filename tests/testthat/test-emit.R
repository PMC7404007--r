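staged_fixture <- function(seed = 31, n = 4, v = 2, spec = messiness_spec(
                             eav_parameter_count = 5)) {
  g <- generate_study(n_subjects = n, visits_per_subject = v, spec = spec,
                      seed = seed)
  list(g = g, res = stage_study(g$config_path))
}

test_that("the i2b2 bundle writes visits separately and keeps modifiers", {
  fx <- staged_fixture()
  b <- fx$res$bundles$i2b2
  expect_true("visits.tsv" %in% names(b$files))
  visit_lines <- strsplit(b$files[["visits.tsv"]], "\n")[[1]]
  expect_equal(length(visit_lines) - 1, nrow(fx$res$visits))

  lab_file <- b$files[["facts_Laboratory.tsv"]]
  lines <- strsplit(lab_file, "\n")[[1]]
  header <- strsplit(lines[1], "\t")[[1]]
  mod_col <- which(header == "modifier_cd")
  mods <- vapply(strsplit(lines[-1], "\t"), `[`, character(1), mod_col)
  n_value_rows <- sum(mods == "@")
  n_lab_facts <- sum(fx$res$facts$entity == "Laboratory")
  expect_equal(n_value_rows, n_lab_facts)
  # two modifier rows (Unit, Norm range) per lab fact, coded in the tree
  expect_equal(sum(mods != "@"), 2 * n_lab_facts)
  expect_true(all(mods[mods != "@"] %in% fx$res$ontology$code))
})

test_that("the invocation descriptor orders ontology before facts", {
  fx <- staged_fixture(seed = 5, n = 2, v = 1)
  inv <- fx$res$bundles$i2b2$files[["invocation.txt"]]
  expect_match(inv, "preceded by loading the ontology")
  expect_lt(regexpr("ontology.tsv", inv)[1], regexpr("facts_", inv)[1])
})

test_that("emitters are deterministic and refuse an empty model", {
  fx <- staged_fixture(seed = 8, n = 3, v = 1)
  res <- fx$res
  b1 <- emit_i2b2_bundle(res$subjects, res$visits, res$facts,
                         res$ontology, res$config)
  b2 <- emit_i2b2_bundle(res$subjects, res$visits, res$facts,
                         res$ontology, res$config)
  expect_identical(b1$files, b2$files)

  empty_subjects <- res$subjects[0, ]
  expect_error(emit_i2b2_bundle(empty_subjects, res$visits, res$facts,
                                res$ontology, res$config),
               class = "clinstage_emit_error")
  expect_warning(emit_i2b2_bundle(res$subjects, res$visits, res$facts[0, ],
                                  res$ontology, res$config),
                 "metadata-only")
})

test_that("meta-attributes flatten into tranSMART attribute variants", {
  cfg <- parse_config(fig4_config_text())
  ptab <- as_source_table(data.frame(PatientID = c("P1", "P2"),
                                     Sex = c("m", "f")), "patients")
  ltab <- as_source_table(data.frame(
    PatientID = c("P1", "P2"),
    Parameter = c("LDL", "LDL"),
    Result = c("140", "3.6"),
    Unit = c("mg/dL", "mmol/L"),
    `Norm range` = c("<130", "<3.4"), check.names = FALSE), "labdata")
  cfg <- expand_eav_entities(cfg, ltab)
  subs <- build_subjects(ptab, cfg)$subjects
  recs <- dplyr::bind_rows(
    widen_declared(ptab, cfg$entities[[1]], cfg)$records,
    denormalize_eav(ltab, cfg$entities[[2]], cfg)$records)
  fb <- assemble_facts(recs, subs, build_visits(NULL, cfg, subs)$visits,
                       cfg = cfg)
  tree <- build_ontology(cfg, clinstage:::profile_attributes(
    recs, list(day_first = TRUE)))
  tm <- emit_transmart_bundle(subs, fb$facts, tree, cfg)
  mapping <- tm$bundle$files[[grep("column_mapping",
                                   names(tm$bundle$files))]]
  expect_match(mapping, "LDL (mg/dL, <130)", fixed = TRUE)
  expect_match(mapping, "LDL (mmol/L, <3.4)", fixed = TRUE)
  expect_equal(tm$aggregation$total_collapsed, 0)
})

test_that("repeated measurements collapse per policy with exact counts", {
  cfg <- facts_fixture_cfg()
  subs <- build_subjects(as_source_table(data.frame(
    PID = "P1", Sex = "m"), "patients"), cfg)$subjects
  visits <- build_visits(as_source_table(data.frame(
    PID = "P1", VID = "V1", Start = "2020-01-01", End = "2020-01-10"),
    "visits"), cfg, subs)
  tab <- as_source_table(data.frame(
    PID = rep("P1", 3), Par = "LDL",
    Val = c("140", "150", "160"),
    Date = c("2020-01-02", "2020-01-08", "2020-01-05")), "labs")
  recs <- denormalize_eav(tab, cfg$entities[[2]], cfg)$records
  fb <- assemble_facts(recs, subs, visits$visits, cfg = cfg)
  tree <- build_ontology(cfg, clinstage:::profile_attributes(
    recs, list(day_first = TRUE)))

  tm_latest <- emit_transmart_bundle(subs, fb$facts, tree, cfg,
                                     policy = "latest")
  expect_equal(tm_latest$aggregation$total_collapsed, 2)
  expect_equal(tm_latest$aggregation$cells$collapsed, 2L)
  # oracle: the surviving value carries the maximum timestamp
  data_file <- tm_latest$bundle$files[[grep("clinical_data",
    names(tm_latest$bundle$files))]]
  expect_match(data_file, "\t150")    # value dated 2020-01-08

  tm_first <- emit_transmart_bundle(subs, fb$facts, tree, cfg,
                                    policy = "first")
  expect_match(tm_first$bundle$files[[grep("clinical_data",
    names(tm_first$bundle$files))]], "\t140")

  tm_mean <- emit_transmart_bundle(subs, fb$facts, tree, cfg,
                                   policy = "mean")
  expect_match(tm_mean$bundle$files[[grep("clinical_data",
    names(tm_mean$bundle$files))]], "\t150")  # mean(140,150,160)
})

test_that("without meta-attributes or repeats the dialects agree", {
  d <- withr::local_tempdir()
  cfg_path <- write_mini_study(d)
  res <- stage_study(cfg_path)
  expect_equal(res$aggregation$total_collapsed, 0)
  expect_equal(res$bundles$i2b2$manifest$counts$facts,
               res$bundles$transmart$manifest$counts$facts)

  out <- withr::local_tempdir()
  write_bundle(res$bundles$transmart, file.path(out, "tm"))
  melted <- melt_transmart(file.path(out, "tm"))
  i2b2_set <- sort(paste(res$facts$subject_id, res$facts$attribute,
                         res$facts$value_chr))
  tm_set <- sort(paste(melted$subject_id, melted$variable, melted$value))
  expect_identical(tm_set, i2b2_set)
})

test_that("mapping files are closed over their data files and ontology", {
  fx <- staged_fixture(seed = 44, n = 3, v = 2)
  b <- fx$res$bundles$i2b2
  onto <- b$files[["ontology.tsv"]]
  onto_codes <- vapply(strsplit(strsplit(onto, "\n")[[1]][-1], "\t"),
                       function(x) x[[6]], character(1))
  for (nm in grep("^mapping_", names(b$files), value = TRUE)) {
    lines <- strsplit(b$files[[nm]], "\n")[[1]][-1]
    for (ln in lines) {
      cells <- strsplit(ln, "\t")[[1]]
      fact_file <- cells[1]
      expect_true(fact_file %in% names(b$files))
      header <- strsplit(strsplit(b$files[[fact_file]], "\n")[[1]][1],
                         "\t")[[1]]
      expect_true(cells[4] %in% header)       # label names a real column
      expect_lte(as.integer(cells[3]), length(header))
    }
  }
  # every concept code used in fact files exists in the ontology file
  for (nm in grep("^facts_", names(b$files), value = TRUE)) {
    lines <- strsplit(b$files[[nm]], "\n")[[1]][-1]
    if (length(lines) == 0) next
    codes <- vapply(strsplit(lines, "\t"), function(x) x[[3]], character(1))
    expect_true(all(codes %in% onto_codes))
  }
})

test_that("write_bundle is atomic-ish, checksummed and refuses clobbering", {
  fx <- staged_fixture(seed = 2, n = 2, v = 1,
                       spec = messiness_spec(eav_parameter_count = 3))
  b <- fx$res$bundles$i2b2
  d <- withr::local_tempdir()
  out <- file.path(d, "bundle")
  manifest_path <- write_bundle(b, out)
  expect_true(file.exists(manifest_path))
  manifest <- jsonlite::read_json(manifest_path)
  for (rel in names(b$files)) {
    on_disk <- readChar(file.path(out, rel),
                        file.size(file.path(out, rel)), useBytes = TRUE)
    Encoding(on_disk) <- "UTF-8"
    expect_identical(on_disk, b$files[[rel]])
    expect_identical(manifest$checksums[[rel]], rlang::hash(on_disk))
  }
  expect_error(write_bundle(b, out), class = "clinstage_io_error")
  expect_silent(write_bundle(b, out, force = TRUE))

  out2 <- file.path(d, "bundle2")
  write_bundle(b, out2)
  f <- names(b$files)[1]
  expect_identical(readBin(file.path(out, f), "raw",
                           file.size(file.path(out, f))),
                   readBin(file.path(out2, f), "raw",
                           file.size(file.path(out2, f))))
})
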