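Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pharmacovigilance pipeline for FAERS-style
    spontaneous adverse-event report databases: reading and writing the
    quarterly '$'-delimited ASCII tables (DEMO, DRUG, REAC, THER, OUTC),
    case-version deduplication, target-drug identification by synonym and
    role code, MedDRA Preferred Term and System Organ Class aggregation,
    fourfold-table disproportionality statistics (reporting odds ratio,
    proportional reporting ratio, information component, empirical Bayes
    geometric mean) with confidence and credibility bounds, chi-square
    testing with Benjamini-Hochberg false-discovery-rate control, composite
    signal flagging, descriptive epidemiology (demographics, outcomes,
    time to onset, annual counts), and a seeded synthetic-report generator
    with planted drug-event associations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
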