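Package: MEscreen
Title: Two-Tissue Screening and Validation Statistics for Metastable
    Epialleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-scale discovery and validation of human
    metastable epialleles (MEs): in-silico SmaI/XmaI (CCCGGG) restriction
    digest and informative-interval enumeration, candidate calling from
    parallel two-tissue methylation-specific amplification microarray
    (MSAM) comparisons, exclusion of candidates confounded by SNPs, copy
    number variants and segmental duplications, genomic-context profiling
    of CpG islands and repeat classes, bisulfite-pyrosequencing validation
    statistics (inter-tissue correlation, monozygotic-twin concordance,
    genotype association, cross-population comparison), a REML
    variance-components model for season-of-conception effects on DNA
    methylation, and a method-of-moments IBD kinship estimator for twin
    verification. Seeded synthetic-data generators with ground-truth
    tables make the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
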