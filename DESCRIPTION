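Package: smokecourse
Title: Time-Course Differential Expression, Cessation Patterns, and
    Metabolome Concordance for Smoke-Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for time-course analyses of chronic
    cigarette-smoke exposure experiments with an embedded cessation arm.
    Implements negative-binomial exact-test differential expression with
    TMM normalization, quantile-adjusted conditional likelihood dispersion
    estimation and independent filtering; directional gene-set enrichment
    with influential-gene extraction; classification of genes and pathways
    into smoking-cessation reversibility patterns; protected polynomial
    time-trend testing over unequally spaced time points; and
    transcriptome-metabolome pathway concordance. Ships a synthetic-data
    generator with planted ground truth emulating a five-time-point
    air-control / smoke-exposed / stop-smoking mouse design, so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
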