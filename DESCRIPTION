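Package: scaQTL
Title: Single-Cell Chromatin Accessibility QTL Mapping with Poisson
    Mixed Models and Topic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for mapping chromatin accessibility quantitative
    trait loci (caQTLs) from single-cell ATAC-seq fragment counts.
    Implements a single-cell Poisson mixed-effects model (sc-PME) with
    donor and library random intercepts, grade-of-membership topic
    modeling of cell states via Poisson non-negative matrix
    factorization with incremental topic expansion, topic-derived cell
    trajectories and along-trajectory differential accessibility,
    dynamic (genotype-by-cell-state interaction) caQTL likelihood ratio
    tests, donor-genotype permutation calibration, Han-Eskin RE2
    multi-study meta-analysis, Wakefield approximate-Bayes-factor
    colocalization, Storey q-value/pi1 sharing statistics, and a
    synthetic-data generator that emulates multi-donor, multi-library,
    multi-study sparse single-cell count structure with planted
    genotype and cell-state effects for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    lme4,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, ATACSeq, Epigenetics, GeneRegulation,
    FunctionalGenomics, GeneticVariability, SNP, Software
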