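Package: mendelmatch
Title: Family-Aware Mendelian Variant Filtering, Phenotype Matching and
    Gene/Variant Matchmaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters annotated sequence variants from family exome or genome
    studies by Mendelian segregation under eight inheritance models (de novo
    and inherited autosomal dominant, autosomal recessive homozygous and
    compound heterozygous, X-linked recessive and dominant, maternal and
    paternal imprinting), with user-tunable minor-allele-frequency, depth,
    intolerance-score and coordinate restrictions. Provides cross-proband
    cohort and oligogenic queries, gene-list and protein-interaction
    neighbourhood filters, phenotype feature search, proband overlap matching
    by the overlap coefficient, differential-diagnosis ranking against a
    disease knowledge table, and a deterministic gene- and variant-level
    matchmaking registry with daily quotas and stored-query replay. A
    seed-driven synthetic fixture generator produces pedigrees, multi-sample
    VCFs, annotation tables and phenotype profiles with a ground-truth
    manifest so every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
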