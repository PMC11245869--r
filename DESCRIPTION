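Package: methylSurv
Title: DNA Methylation Biological Age, Differential Methylation and
    Mortality Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of EPIC-like DNA methylation beta
    matrices in a matched case-control survival design: sample and probe
    quality-control filtering, a coefficient-file-driven epigenetic clock
    and EpiScore engine (including principal-component clocks),
    reference-based blood cell deconvolution, a two-stage
    residual-outcome regression test for DNAm estimators with IQR
    outlier handling and Benjamini-Hochberg adjustment, propensity-score
    matching, Cox proportional-hazards association, differential
    methylation and variability calling with empirical-Bayes variance
    moderation, spatially-correlated p-value combination for region
    calling, and Fisher over-representation on GMT gene sets. A seeded
    synthetic-data generator reproduces the statistical structure the
    pipeline assumes, so the whole analysis is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival,
    mclust,
    pracma,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
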