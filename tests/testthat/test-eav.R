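test_that("lab-export rows denormalize into per-parameter records", {
  cfg <- parse_config(fig4_config_text())
  tab <- fig4_table()
  entity <- cfg$entities[[2]]
  out <- denormalize_eav(tab, entity, cfg)
  expect_equal(nrow(out$records), 2)

  ldl <- out$records[out$records$attribute == "LDL", ]
  expect_equal(ldl$value, "140")
  expect_equal(ldl$meta[[1]], c(Unit = "mg/dL", `Norm range` = "<130"))

  crp <- out$records[out$records$attribute == "CRP", ]
  expect_equal(crp$value, "0.5")
  # empty norm-range cell leaves the key absent
  expect_equal(crp$meta[[1]], c(Unit = "mg/L"))
})

test_that("rows with missing parameter or value are skipped and counted", {
  cfg <- parse_config(fig4_config_text())
  tab <- as_source_table(data.frame(
    PatientID = c("P1", "P1", "P2"),
    Parameter = c("LDL", "", "CRP"),
    Result = c("", "5", "1.1"), Unit = "U",
    `Norm range` = "", check.names = FALSE), "labdata")
  out <- denormalize_eav(tab, cfg$entities[[2]], cfg)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$skipped[["missing_parameter"]], 1L)
  expect_equal(out$skipped[["missing_value"]], 1L)
})

test_that("two parameter columns combine into the record's attribute", {
  txt <- sub("parameter_columns: \\[Parameter\\]",
             "parameter_columns: [Parameter, Material]",
             fig4_config_text())
  cfg <- parse_config(txt)
  tab <- as_source_table(data.frame(
    PatientID = "P1", Parameter = "Glucose", Material = "Serum",
    Result = "95", Unit = "mg/dL", `Norm range` = "70-110",
    check.names = FALSE), "labdata")
  out <- denormalize_eav(tab, cfg$entities[[2]], cfg)
  expect_equal(out$records$attribute, "Glucose|Serum")
})

test_that("declared-attribute widening emits one record per filled cell", {
  cfg <- parse_config(paste(
    "study: S",
    "sources:",
    "  p: {path: p.csv, role: patient-file, key_columns: [ID]}",
    "entities:",
    "  - name: E",
    "    anchor: patient",
    "    source: p",
    "    attributes:",
    "      - {name: A, column: A}",
    "      - {name: B, column: B}",
    "      - name: C",
    "        column: C",
    "        meta: [{name: Qual, column: Q}]",
    sep = "\n"))
  tab <- as_source_table(
    data.frame(ID = "P1", A = "1", B = "", C = "3", Q = ""), "p")
  out <- widen_declared(tab, cfg$entities[[1]], cfg)
  expect_equal(nrow(out$records), 2)
  expect_equal(out$skipped[["missing_value"]], 1L)
  crec <- out$records[out$records$attribute == "C", ]
  expect_equal(crec$meta[[1]], character())  # empty meta cell: absent key

  out0 <- widen_declared(as_source_table(
    data.frame(ID = character(), A = character(), B = character(),
               C = character(), Q = character()), "p"),
    cfg$entities[[1]], cfg)
  expect_equal(nrow(out0$records), 0)
})

test_that("denormalization equals the brute-force pivot oracle", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n_param_cols <- sample(1:2, 1)
      df <- random_eav_df(n_rows = sample(1:20, 1),
                          n_params = sample(1:5, 1),
                          n_param_cols = n_param_cols)
      pcols <- if (n_param_cols == 2) c("Parameter", "Material")
               else "Parameter"
      cfg <- eav_cfg_for(pcols)
      tab <- as_source_table(df, "tab")
      got <- denormalize_eav(tab, cfg$entities[[2]], cfg)
      want <- eav_pivot_oracle(df, pcols, "Result",
                               list(list(name = "Unit", column = "Unit")))
      expect_identical(records_as_strings(got$records), want$records)
      expect_identical(got$skipped[["missing_parameter"]], want$skip_param)
      expect_identical(got$skipped[["missing_value"]], want$skip_value)
      # conservation: records + skips == rows
      expect_equal(nrow(got$records) + sum(got$skipped), nrow(df))
    }
  })
})

test_that("row order does not change the multiset of records", {
  withr::with_seed(7, {
    df <- random_eav_df(15, 4, 1)
    cfg <- eav_cfg_for("Parameter")
    base <- denormalize_eav(as_source_table(df, "tab"),
                            cfg$entities[[2]], cfg)
    perm <- sample(nrow(df))
    shuffled <- denormalize_eav(as_source_table(df[perm, ], "tab"),
                                cfg$entities[[2]], cfg)
    strip_rows <- function(r) {
      sort(paste(r$attribute, r$value,
                 clinstage:::meta_signature(r$meta), sep = "|"))
    }
    expect_identical(strip_rows(shuffled$records),
                     strip_rows(base$records))
  })
})
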