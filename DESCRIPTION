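Package: wssgblup
Title: Weighted Single-Step Genomic BLUP and Window-Based GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic evaluation and weighted single-step
    genome-wide association analysis for low-heritability livestock
    traits such as calving interval.  Builds pedigree numerator
    relationship matrices (tabular A, Meuwissen-Luo inbreeding,
    Henderson's sparse A-inverse), VanRaden genomic relationship
    matrices with per-SNP variance weights, and the combined
    single-step H-inverse; solves Henderson's mixed-model equations
    for animal and repeatability models with prediction error
    variances and accuracies; estimates variance components by
    AI-REML with monotone EM fallback; iterates the weighted
    single-step scheme that back-solves SNP effects from genomic
    breeding values and reweights SNP variances; and scans sliding
    SNP windows for the percentage of additive genetic variance they
    explain.  Includes a gene-dropping simulator producing pedigrees,
    genotypes and phenotypes with known truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
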