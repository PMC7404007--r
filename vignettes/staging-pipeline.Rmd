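---
title: "Declarative staging for clinical data warehouses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative staging for clinical data warehouses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinstage)
```

## The staging model

`clinstage` implements the staging phase of a *meta-loading* pipeline for
clinical and translational data warehouses. The user does not script a
loading process; they declare an entity-relationship model over their
input files, and the compiler derives everything else — cleansing steps,
the EAV denormalization, the concept ontology, and the staging file sets
for an i2b2-oriented and a tranSMART-oriented back-end loader. The actual
database load is performed by those back-end tools and is out of scope
here; each bundle instead carries an invocation descriptor stating how the
loader would be run (for i2b2, ontology loading must precede fact
loading).

The pipeline assumes only that input data are tabular; that every line
carries data for one patient, visit or encounter; that those are
identified by (composite) keys or timestamps; that exactly one file
describes the patients or probands, while a visit file is optional; and
that entities relate to patients, visits or encounters. Everything else —
encodings, delimiters, number and date formats, column types — is
detected.

Three object kinds flow through the pipeline, all ordinary tibbles:
**source tables** (parsed files as character cells with encoding/dialect
provenance and original line numbers), **attribute records** (one
observation candidate per row: entity, attribute, subject/visit keys,
verbatim value, meta-attribute map, timestamp token), and **facts** (typed
values bound to canonical subject and visit ids and a concept path, with
modifiers).

## Ingestion

A byte-order mark decides the encoding outright. Otherwise a statistical
detector proposes candidates; candidates that do not decode the bytes are
discarded, valid UTF-8 always wins, and remaining ties fall to the fixed
priority UTF-8 > ISO-8859-1 > UTF-16 so that identical bytes always give
identical decisions. Delimiter sniffing scores the candidates `, ; TAB |`
on the first 100 lines by column-count consistency under quoting; a header
line is inferred from type contrast between the first line and the body.
Ragged rows are padded (short) or truncated (long) and always logged with
their line number; `strict` mode turns both into errors. The invariance
this buys is testable and tested: one logical study serialized under
{UTF-8, UTF-8 with BOM, ISO-8859-1} × {comma, semicolon, tab} stages to
byte-identical bundles.

## Cleansing and typing

The tunable parameters, their defaults, and the reasoning:

| Parameter | Default | Why |
|---|---|---|
| missing tokens | `"" NA N/A NULL - .` (case-insensitive, trimmed) | the values empirically used by clinical export systems; configurable |
| numeric rule | **100 %** of non-missing cells must parse | a single stray string demotes the column — silently coercing clinical values is worse than a categorical fallback |
| decimal comma | accepted only if no cell contains `.` and all match digits-comma-digits | avoids thousands-separator ambiguity |
| date threshold | ≥ 95 % of non-missing cells parse | tolerates isolated malformed stamps without surrendering the column |
| categorical ceiling | distinct ≤ max(20, 5 % of rows) | larger vocabularies are free text |
| ambiguous numeric dates | day-first | the German-locale sources this pipeline grew up on; configurable |
| duplicate policy | keep-first + conflict log | lossless in count, explicit about what was discarded |
| tranSMART aggregation | latest timestamp | see below |

Timestamps carry an explicit **precision** (`year`, `month`, `day`,
`minute`, `second`) equal to the granularity present in the token. The
instant stored is the *start of the precision window* (Jan 1, first of
month, midnight): a conventional, monotone representative that emitters
can disclose alongside the precision, so a reader can always tell imputed
from observed components. A visit without an explicit end spans its start
token's precision window.

"Inconsistent timestamps" are handled in two places: a visit whose end
precedes its start is rejected with a reason code, and a key-linked fact
whose timestamp falls outside its visit window is kept but logged. The
alternative — dropping such facts — was rejected as lossy where the
inconsistency may well be in the visit file, not the fact.

## EAV denormalization

Each distinct observed parameter combination becomes one generated
attribute; multiple parameter columns (e.g. analyte × material) are joined
with a configurable separator, `|` by default, chosen because it is
unambiguous and rare in clinical labels. Labels are whitespace-normalized
but compared **case-sensitively**: silently merging `pH` and `PH` would
conflate clinically distinct codes. A generated name colliding with a
declared attribute is a hard error, since a silent overwrite would corrupt
the ontology. Expansion is idempotent and order-independent (generated
attributes are re-derived and sorted by name), and a parameter value seen
in data but missed by expansion (possible with multi-file patterns) is
expanded on the fly and logged rather than rejected — agility over
strictness.

## Visit linkage

Facts link to visits by visit key when one is present; otherwise by
timestamp containment in *exactly one* of the subject's visit windows.
Zero or two-plus candidate windows leave the fact unlinked, with the
ambiguity logged: linkage is never guessed. Timestamp-only *subject*
identification is not supported — with no key there is no sound way to
distinguish subjects — and is flagged at validation instead.

## Ontology and codes

Concept paths are `\study\entity\attribute\` with one modifier node per
meta-attribute beneath its concept. Path segments are sanitized
(backslash, slash, control characters → `_`; 200-character cap per
segment, respecting warehouse path limits); a collision created by
sanitization is an error, never a merge. Sibling order is lexicographic —
the one total order that makes the emitted tree byte-identical across
runs. Node codes are the first 16 hexadecimal characters of a
deterministic 128-bit hash of the full path: stable across runs and
machines without a database sequence, local to each path (adding nodes
never changes existing codes), and injective in practice, with an
automatic fallback to the full digest should a truncated collision ever
occur.

## The two dialects

The back-end formats are pinned to documented conventions of the two
loader families and defined, for testing purposes, by the package's own
bundle reader: tab-separated, UTF-8, LF throughout.

The **i2b2 dialect** is lossless. Facts are written per entity in long
observation form — a value row (modifier code `@`) plus one row per
modifier, tied together by an instance number — with subjects in their own
file, visits written separately, column/word mapping files, and the coded
ontology. An independent reader reconstructs the exact fact multiset from
the written files; that round trip is the package's central acceptance
property.

The **tranSMART dialect** is lossy by the target platform's nature, and
the loss is made explicit. Meta-attributes have no native representation,
so they flatten into attribute *variants* (`LDL (mg/dL, <130)`; meta
values in declared order, `n/a` for a missing one) — this loses no facts.
Repeated measurements per (subject, visit, variable) do not fit the wide
clinical-data format, so they collapse under a configurable policy:
`latest` timestamp by default (untimed values sort earliest, provenance
order breaks ties), with `first` and `mean` (numeric only) as
alternatives. Every collapse is counted in an aggregation report, and the
identity *i2b2 facts − tranSMART facts = collapse total* is asserted by
the tests — the fact loss between platforms is exactly reconciled, not
merely observed.

Bundles are written atomically (temporary directory, then a single
rename), refuse a non-empty target without `force`, and carry a manifest
with per-file checksums and run parameters.

## The synthetic generator

Since the institutional datasets this class of pipeline is built for
cannot be shared, the package generates its own studies, covering the
three shapes such pipelines must absorb in miniature: a flat structured
questionnaire, longitudinal EAV laboratory data with repeated
measurements per visit, and highly structured visit-level billing data —
plus patient demographics with non-ASCII German place names to keep the
encoding path honest. All randomness flows from a single integer seed;
identical seeds give byte-identical files. Value distributions are
deliberately simple and documented rather than clinically calibrated: lab
values log-normal around per-parameter reference values, categories
uniform over small sets, lab dates uniform within their visit's window.

Messiness is injected per laboratory row at configurable rates —
duplicated rows, blanked results, month-precision dates, rows missing
their trailing field — and every injection is recorded in a defect ledger
alongside the expected post-staging facts. The clean defaults (50
subjects, 3 visits per subject, 20 laboratory parameters in the test
configuration) keep the full test suite and the acceptance script
comfortably fast on one CPU; the compactness property deliberately scales
the parameter count to 1000 with few subjects instead.

What passing these tests shows is that the pipeline is exact under the
defect classes it claims to handle; what they cannot show is robustness
to real-world pathologies the generator does not emulate — inconsistent
per-row date locales within one column, semantically duplicated (rather
than byte-duplicated) records, or free-text value columns mixing units
into the value. Those remain the user's responsibility to inspect via the
anomaly log.

## Design choices where the design was open

* **Configuration syntax.** YAML with sections `study`, `sources`,
  `entities`, `filters`, `options`: human-editable, diff-friendly, and
  compact — a few dozen lines drive studies whose staging output runs to
  tens of thousands of lines. Unknown keys are rejected so typos fail
  loudly. The grammar is this package's own; it is a re-expression of the
  declarative-annotation idea, not byte-compatible with any other tool's
  configuration format.
* **Canonical ids.** Sanitized source keys joined by `_`, prefixed with
  the study code (`SYNTH_P001`, `SYNTH_V_P001_V1`): stable across runs,
  readable, and reversible enough for debugging. Pseudonymization is
  explicitly out of scope.
* **Duplicate identity includes modifiers.** Two lab results differing
  only in unit are different facts, not duplicates.
* **Validation reports, never raises.** `validate_config()` returns a
  findings table; only the orchestrator turns a non-empty report into a
  refusal to run. This keeps validation usable as an interactive check.

## Known limitations

No omics/high-dimensional data; no terminology mapping to standard
vocabularies; no anonymization or pseudonymization; no incremental
loading — staging always compiles the full study. The emitted dialects
track documented loader conventions but are verified against this
package's own reader, not against live database loads.
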