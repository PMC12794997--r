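Package: faersdpa
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for FAERS-style spontaneous adverse-event
    report data: a synthetic report generator with planted signal structure,
    readers and writers for the quarterly dollar-delimited ASCII tables,
    report cleaning (case-level deduplication, drug-name normalization,
    target-event filtering, primary-suspect restriction), four-algorithm
    disproportionality analysis (reporting odds ratio, proportional
    reporting ratio, BCPNN information component, and the
    observed-to-expected EBGM) with a composite signal rule and
    label-novelty flagging, Weibull time-to-onset modelling with
    failure-type classification, and cohort, trend, ranking and
    cross-database summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
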