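Package: ceindex
Title: Coastal Ecosystem Services Index for Tidal-Flat Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores coastal ecosystem services for multi-site tidal-flat
    assessments. For each service at each site the package computes a
    present status normalized against a cross-site reference point (with
    outlier screening), a five-year trend score with regression confidence
    intervals, pressure-resilience scores for the environmental factors of
    a user-declared conceptual model, a likely near-term future status, a
    service score on a 0-100 scale, and a sustainability score. Diagnostic
    reports identify the environmental factors that need countermeasures.
    A synthetic panel generator with known ground truth supports testing
    and demonstration without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
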