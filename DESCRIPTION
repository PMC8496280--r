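Package: mpeqtl
Title: Expression QTL Mapping in Multiparental Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Expression genetics toolkit for multiparental recombinant
    inbred line (mpRIL) populations, modelled on a four-founder
    Caenorhabditis elegans cross. Provides fpkm normalization and
    expression filtering, parental differential expression (Tukey HSD)
    with permutation false-positive rates, transgressive segregation
    scoring, kinship-based narrow-sense heritability by restricted
    maximum likelihood with per-gene permutation thresholds,
    single-marker eQTL mapping with a permutation FP/TP threshold,
    SNP-distribution-pattern (SDP) stratified cis/trans classification,
    trans-band hotspot detection, hypergeometric GO enrichment, and
    cross-study eQTL overlap. A genotype and expression simulator with a
    planted-effect truth ledger makes every stage testable without the
    original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
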