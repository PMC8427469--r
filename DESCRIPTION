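Package: tsoPGS
Title: Trait-State-Occasion Models of Common and Substance-Specific
    Liability with Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetically informed modelling of common versus
    substance-specific liability to substance use. Implements clumping
    and p-value thresholding of GWAS summary statistics into
    standardised polygenic scores, trait-state-occasion (TSO)
    structural equation models of repeated substance-use scores
    estimated by full-information maximum likelihood with sandwich
    robust standard errors, fit indices (CFI, RMSEA, SRMR), variance
    decomposition, and single- and multi-polygenic-score latent
    regressions with false-discovery-rate based selection. Ships a
    synthetic-data generator with known ground truth (LD-blocked
    genotypes, noisy summary statistics, bounded count-like phenotypes
    with latent common/specific/occasion structure and missingness)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
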