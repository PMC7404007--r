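# clinstage

Declarative staging compiler for clinical and translational data
warehouses.

## The problem

Clinical and translational research projects routinely need the same data
in more than one warehouse at once — an i2b2 instance for longitudinal,
timestamped clinical queries and a tranSMART-style platform for structured
research analysis. The loading tools for those platforms make strong and
mutually incompatible assumptions about the structure and cleanliness of
their input: specific date formats, no missing values, one value per
subject and variable, pre-annotated ontology codes. Real exports from
hospital and study systems violate all of these: they arrive in mixed
encodings and delimiter dialects, carry duplicates, partial dates and empty
cells, and often store observations in entity–attribute–value (EAV) form —
a long table in which each row names a parameter (`Parameter`, `Result`,
`Unit`, `Norm range`, …) rather than owning a column.

`clinstage` closes that gap with a *meta-loading* approach: instead of
telling a loader *how* to process each file, the user writes a compact
declarative configuration describing *what* the data are — an
entity-relationship model mapped onto the input columns. The compiler then

* ingests the raw files, detecting character encoding and delimiter
  dialect automatically;
* normalizes missing values, infers column types (numeric / categorical /
  date / text) and parses timestamps with explicit precision (`2019-03` is
  kept as a month, not silently promoted to a day);
* denormalizes EAV tables: every distinct parameter (or combination of
  parameter columns, e.g. analyte × material) becomes a generated
  attribute, annotated with its meta-attributes — the i2b2 *modifiers*;
* builds the canonical subject / visit / fact model, linking facts to
  visits by composite keys or by timestamp containment, detecting
  duplicates and inconsistent timestamps;
* derives the prefix-closed concept ontology `\study\entity\attribute\`
  with stable 16-hex-digit node codes; and
* compiles everything into two back-end staging dialects from the *same*
  configuration: an i2b2-oriented batch-loader bundle (facts in long
  observation form with coded modifiers, visits written separately,
  ontology files, mapping files, invocation descriptor) and a
  tranSMART-oriented study directory (wide clinical data file plus column
  and word mappings, with meta-attributes flattened into attribute
  variants and repeated measurements collapsed under an explicit, reported
  aggregation policy).

Every cleansing step is logged with row provenance, and every count in the
run report satisfies an exact conservation identity, so nothing is lost
silently.

## Worked example

The package ships a deterministic synthetic-study generator (patients,
visits, a questionnaire, visit-level billing codes, and an EAV laboratory
file) with exact ground truth, so the whole pipeline can be exercised
without access to clinical data:

```r
library(clinstage)

study  <- generate_study(n_subjects = 20, visits_per_subject = 2, seed = 42,
                         dir = file.path(tempdir(), "demo"))
result <- stage_study(study$config_path, out_dir = file.path(tempdir(), "staged"))
result
#> <staging_result> study: SYNTH
#>   subjects: 20 | visits: 40 | facts: 980 | ontology nodes: 72
#>   duplicates dropped: 0 | conflicts: 0 | anomalies: 0
#>   bundles: i2b2, transmart
```

20 subjects × 2 visits × 20 lab parameters plus 5 demographic/questionnaire
facts per subject and 2 billing facts per visit give the 980 facts; the 72
ontology nodes are 1 study folder, 4 entity folders, 27 concepts and 40
modifier nodes. Individual facts are typed, timestamped, visit-linked
tibble rows:

```r
dplyr::select(head(subset(result$facts, entity == "Laboratory"), 3),
              subject_id, visit_id, attribute, value_chr, timestamp)
#> # A tibble: 3 × 5
#>   subject_id visit_id        attribute value_chr timestamp
#>   <chr>      <chr>           <chr>     <chr>     <dttm>
#> 1 SYNTH_P001 SYNTH_V_P001_V1 LDL       117.33    2018-02-04 00:00:00
#> 2 SYNTH_P001 SYNTH_V_P001_V1 HDL       46.18     2018-02-05 00:00:00
#> 3 SYNTH_P001 SYNTH_V_P001_V1 CRP       3.94      2018-02-04 00:00:00

glance(result)
#> # A tibble: 1 × 8
#>   study subjects visits facts ontology_nodes duplicates_dropped anomalies targets
#>   <chr>    <int>  <int> <int>          <int>              <int>     <int> <chr>
#> 1 SYNTH       20     40   980             72                  0         0 i2b2+transmart
```

`tidy(result)` returns every pipeline counter as a tibble and
`autoplot(result)` draws them; `read_i2b2_bundle()` re-reads a written
bundle and reconstructs the exact fact multiset — the package's central
lossless-staging guarantee.

A thin command-line wrapper is installed under `inst/cli/`:

```sh
Rscript inst/cli/clinstage fixtures --out demo --subjects 20 --visits 2 --seed 42
Rscript inst/cli/clinstage stage --config demo/study.yaml --target both --out staged
```

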