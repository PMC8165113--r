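Package: valvesex
Title: Sex-Stratified Transcriptomic Analysis of Aortic Valve Calcification
Version: 0.1.0
Authors@R: person("Valve", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for sex-stratified analysis of aortic valve
    transcriptomes across degrees of calcification. Provides propensity-score
    matching of male and female patients with standardized-difference balance
    diagnostics, a matched-pair 2x2 concordance statistic for sex and tissue
    effects, projection-score guided variance filtering with principal
    component analysis, paired and tissue-adjusted differential expression
    with Benjamini-Hochberg false discovery control and fold-change filtering,
    genetic-algorithm wrapper feature selection with nested cross-validated
    random-forest fitness, and a six-classifier calcification prediction bench
    with node-improvement importance and pure-tree extraction. A synthetic
    cohort generator with planted effects makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    FNN,
    MASS,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
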