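Package: cholnet
Title: Integrative Differential Expression and Cholesterol-Sensing Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomics workflow for identifying
    cholesterol-sensing genes and their regulatory network. Implements
    permutation-based differential-expression testing for tiny replicated
    two-group designs (pooled-variance t and log2-median-ratio statistics,
    gene-pooled or per-gene permutation nulls, Storey q-values, Stouffer
    combination of per-test FDRs), fold-change calling and 8-way pattern
    grouping for unreplicated two-timepoint designs, cross-dataset
    ortholog-mapped sign-concordance integration with discordant-set
    extraction, hypergeometric gene-set over-representation, and
    DEG-seeded interaction-network construction with neighbor pruning and
    degree-centrality ranking of regulators. Ships synthetic-data
    generators that emulate the statistical structure of the designs so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
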