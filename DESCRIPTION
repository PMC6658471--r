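Package: prsportability
Title: Cross-Ancestry Portability and Construction-Choice Analysis of Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how polygenic risk scores (PRS) transfer across
    human populations. Implements clumping + thresholding score construction
    (allele harmonization, greedy LD clumping against a reference panel,
    p-value thresholding, additive scoring over a factorial methods grid),
    ancestry principal-component analysis with long-range-LD region exclusion
    and PRS-PC correlation scans, a within-study meta-analysis that normalizes
    non-European effect sizes to the matched European baseline, per-population
    score-distribution summaries with a between-population dispersion
    statistic, and population-level PRS versus phenotype correlations. A
    synthetic-data module generates multi-population genotypes under the
    Balding-Nichols drift model with block LD, quantitative phenotypes,
    discovery GWAS summary statistics with optional uncorrected-stratification
    bias, and study-comparison fixtures, so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    VariantAnnotation,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
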