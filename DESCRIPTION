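Package: surfscreen
Title: Screening Chromosome Proteomes for Cell-Surface-Accessible Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening chromosome-scoped proteomes for
    plasma-membrane and cell-surface-accessible protein targets, and for mapping
    such targets across species. Provides redundancy filtering of multi-transcript
    UniProt proteome tables against Ensembl-style canonical-transcript mappings,
    merging of UniProt and eggNOG-mapper Gene Ontology annotations with evidence
    tracking, transmembrane-topology-informed target classification from a fixed
    catalogue of plasma-membrane and cell-surface GO terms, GO-term
    overrepresentation testing (one-sided Fisher's exact test with Bonferroni
    correction and fold enrichment), global pairwise protein alignment with affine
    gap penalties and a percent-similarity statistic over aligned columns,
    codified cross-species curation rules, cross-referencing against a sperm
    proteome reference list, and a fully self-contained synthetic-data generator
    with ground-truth ledgers for offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
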