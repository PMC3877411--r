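Package: HardyMI
Title: Hardy-Weinberg Testing with Multiple Imputation of Missing Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical inference for Hardy-Weinberg proportions when
    genotype calls are missing. Estimates the inbreeding coefficient with
    its large-sample variance, runs chi-square and exact tests for
    Hardy-Weinberg proportions, diagnoses the missing-completely-at-random
    assumption from allele intensities and correlated markers, multiply
    imputes missing genotype calls with ridge-penalized multinomial logit
    models inside a chained-equations engine, and pools per-imputation
    estimates with Rubin's rules into tests, confidence intervals and
    missing-information statistics. Includes a synthetic-panel generator
    with controllable inbreeding, linkage disequilibrium, intensity
    clusters and missingness mechanisms, and a simulation harness
    comparing discarding against imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    nnet,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: SNP, Genetics, StatisticalMethod, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
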