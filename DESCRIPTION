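Package: methylCD8
Title: Differential Methylation and Disease-Activity Scoring for EPIC-Like
    CD8+ T-Cell Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for Illumina EPIC-like DNA methylation
    beta-value matrices from sorted CD8+ T cells, built around a
    RangedSummarizedExperiment container. Provides probe quality-control
    filtering, beta/M transforms, probe-type quantile normalization,
    parametric empirical-Bayes batch correction, empirical-Bayes moderated
    t-tests for differentially methylated positions (DMPs), kernel-smoothed
    differentially methylated region (DMR) calling with Stouffer, Fisher and
    harmonic-mean combined statistics, functional genomic distribution tables,
    hypergeometric over-representation analysis on GMT gene sets, and a
    healthy-control-standardized methylation disease-activity score that is
    correlated with the PASI skin score. A seeded synthetic-cohort generator
    with planted DMPs, DMRs, batch effects and activity-linked CpGs makes
    every stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
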