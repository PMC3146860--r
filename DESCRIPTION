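Package: accelpool
Title: Standardized Reduction and Pooling of Legacy Accelerometer Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reducing legacy uniaxial Actigraph count
    files into harmonized physical-activity outcome variables and pooling them
    with phenotype data across studies. Reads and writes plain-text .dat count
    files, reconstitutes headerless time-stamped count tables, flags spurious
    and temporally shifted recordings (saturation plateaus, non-return-to-
    baseline floors, whole-hour clock shifts), reintegrates sub-minute epochs
    to 60 s, normalizes recordings spanning daylight-saving events, segments
    wear from non-wear with an interruption-tolerant zero-run rule, summarizes
    intensity minutes under configurable cutpoint sets with bout and clock-
    window accounting, tabulates valid-day distributions, and builds an
    anonymized long-format pooled database. Ships a seeded synthetic-cohort
    generator with ground-truth labels so every stage is testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
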