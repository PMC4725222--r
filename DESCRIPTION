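Package: gwaset
Title: Competitive Gene-Set Enrichment Analysis for Quantitative-Trait GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for testing whether an a-priori gene set
    is enriched for association with a quantitative phenotype in genome-wide
    association data. Implements genotype and sample quality control,
    derivation of composite cognitive phenotypes by principal components and
    age/sex residualisation, additive single-marker association with ancestry
    covariates, gene-based association by the sum of per-SNP chi-square
    statistics with an LD-aware simulated null, greedy LD clumping of
    association peaks into genomic intervals, and a competitive gene-set test
    based on matched-interval permutation with a bootstrap correction for
    testing many correlated gene sets. A synthetic cohort generator with
    block-wise linkage disequilibrium, Hardy-Weinberg genotypes and a
    one-factor phenotype battery makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
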