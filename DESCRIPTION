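Package: castemeth
Title: Caste Methylome Analysis for Low-Methylation Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for whole-genome bisulfite sequencing (WGBS)
    analysis of social-insect caste comparisons with very sparse CpG methylation.
    Reads Bismark-style coverage tables and feature annotation, estimates bisulfite
    conversion efficiency from an unmethylated lambda spike-in, applies coverage
    filters, assigns binary methylation status per CpG per sample with a
    two-component binomial/beta-binomial mixture fitted by EM under local
    false-discovery-rate control, computes weighted methylation levels over genes
    and features, tests site-level differential methylation between castes by
    binomial logistic regression with a colony covariate, makes dual-threshold
    gene-level differential-methylation calls, integrates methylation with gene and
    exon expression (binned contrasts, mixed models, set-overlap tests), performs
    hypergeometric GO enrichment, and builds reciprocal-best-hit ortholog sets for
    cross-species comparison. A synthetic-data generator with ground-truth labels
    supports power and calibration studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    lmerTest,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
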