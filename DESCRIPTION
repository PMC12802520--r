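Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    spontaneous adverse-event report data in the style of FAERS extracts:
    report ingestion in wide and long interchange dialects, FDA-style case
    deduplication, primary-suspect filtering, MedDRA preferred-term
    validation, 2x2 contingency tables, and four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio with
    chi-square, the BCPNN information component, and the MGPS empirical
    Bayes geometric mean) with their confidence bounds, significance
    criteria, and signal-intensity grading. Includes signal exclusion and
    ranking, system-organ-class aggregation, descriptive report summaries,
    Naranjo causality scoring, and a seeded synthetic-report generator with
    planted disproportionality for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
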