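Package: sepqtl
Title: Repeated-Measures cis-eQTL and Co-Expression Module QTL Mapping in Sepsis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping genetic regulation of gene
    expression in critically ill patient cohorts with serial sampling.
    Implements random-intercept linear mixed model cis-eQTL scans with
    hierarchical multiple-testing correction and an effective-test estimator,
    forward-backward conditional discovery of independent signals,
    genotype-by-context interaction tests with permutation calibration,
    empirical-Bayes sharing of effects between conditions, transcription
    factor binding-site alteration and regulon-activity analyses,
    co-expression module discovery (biweight midcorrelation, spatial
    quantile normalization, topological overlap, tree cutting), and module
    eigengene QTL mapping with replication, sensitivity, quasi-Bayesian
    mediation and approximate-Bayes-factor colocalization. A synthetic
    cohort generator with planted effects provides a ground-truth surface
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
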