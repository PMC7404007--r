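Package: clinstage
Title: Declarative Staging Compiler for Clinical and Translational Data Warehouses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles heterogeneous tabular clinical and research data plus a
    compact declarative entity-relationship configuration into cleansed,
    denormalized staging bundles for i2b2-oriented and tranSMART-oriented
    back-end loaders. Ingestion detects character encodings and delimiter
    dialects automatically; entity-attribute-value (EAV) tables are
    denormalized into per-parameter concepts annotated with meta-attributes;
    column types, timestamps with explicit precision, missing values and
    duplicates are handled with full traceability; a prefix-closed concept
    ontology with stable codes is derived from the model. A deterministic
    synthetic study generator with controllable messiness and exact ground
    truth supports end-to-end testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
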