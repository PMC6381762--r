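Package: bsfsdem
Title: Blockwise Site Frequency Spectrum Demographic Inference for Two Genomes
Version: 0.1.0
Authors@R:
    person("bsfsdem", "developers", email = "bsfsdem@example.org", role = c("aut", "cre"))
Description: Tabulates the blockwise folded joint site frequency spectrum
    (bSFS) from diploid genotype calls of one individual per species,
    computes analytic probabilities of per-block mutational configurations
    under a grid of divergence, isolation-with-migration and admixture
    models of the structured coalescent, selects among models by
    linkage-corrected composite-likelihood AIC, and rescales the estimates
    to demographic units. Ships a structured-coalescent simulator that
    doubles as a Monte-Carlo oracle for the analytic likelihood and as a
    generator of VCF/BED/FASTA test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
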