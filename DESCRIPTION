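Package: rumenherit
Title: Heritability, Co-Occurrence and Trait Prediction for Dam-Lamb Rumen Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pedigree-based heritability of rumen
    bacterial amplicon sequence variants (ASVs) in dam-lamb pairs. Provides
    ASV-table filtering, rarefaction, diversity and ordination statistics;
    Henderson numerator relationship matrices and their direct inverses;
    average-information REML estimation of additive, maternal and residual
    variance components of per-ASV log relative abundances with delta-method
    standard errors; screening of heritable taxa; compositionally aware
    SparCC co-occurrence networks with MCODE cluster detection and
    hub/keystone calls; Spearman associations of ASVs with growth traits and
    rumen fermentation parameters; litter-stratified random-forest
    classification of high versus low growth-trait groups; and a synthetic
    population generator with known variance components for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ape,
    igraph,
    ranger,
    pROC,
    jsonlite,
    phyloseq
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
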