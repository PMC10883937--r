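Package: ethnocurate
Title: Harmonisation and Quality Audit of Ethnicity Codes in Linked
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating self-reported ethnicity data across linked
    primary-care and hospital record sources. Provides a three-level
    classification hierarchy (fine-grained clinical-terminology concepts,
    the 19 NHS A-Z ethnicity categories, and six high-level census groups
    under alternative aggregation conventions), a source-prioritisation
    decision tree that resolves one ethnicity per person, a synthetic
    cohort generator that emulates the statistical structure of
    England-wide records (record multiplicity, conflicting codes,
    informative missingness), and audit reports covering completeness,
    consistency, co-occurring code pairs, granularity, and descriptor
    diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
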