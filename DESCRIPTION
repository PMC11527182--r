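Package: seedcor
Title: Seed-Gene Correlation Screening and Rare-Disease Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a normalized probe-level expression matrix for genes
    co-expressed with a single seed gene and carries the resulting signed,
    threshold-laddered gene lists through gene-set enrichment to rare-disease
    and candidate-gene calls. Provides Jarque-Bera normality screening with an
    auditable exclusion ledger, Pearson correlation against the seed probe with
    a Bonferroni-adjusted two-tail t filter, probe-to-gene resolution with
    duplicate-probe collapse, hypergeometric over-representation analysis of
    GMT libraries with Benjamini-Hochberg adjustment, disorder selection by
    smallest viable list and unique discrimination, causal-gene augmentation
    for ontology-supported novel-gene calling, and bootstrap support for
    correlation-distance clustering. A synthetic-data generator with planted
    correlation structure, disease terms, and novel genes supplies ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
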