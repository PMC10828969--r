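Package: sibherit
Title: Sibling-Design Heritability of Rare Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Liability-threshold variance-component analysis of rare binary
    traits using full- and half-sibling pairs drawn from registry-style
    pedigree data. Builds family clusters from parent links, performs
    randomized one-pair-per-cluster selection with paternal half-sibling
    priority, collapses pair phenotypes into exchangeable 2x2 tables,
    estimates tetrachoric correlations by maximum likelihood (optionally
    with a birth-year-adjusted threshold), and fits ACE/AE biometric models
    jointly across relationship strata with delta-method confidence
    intervals. Includes a synthetic registry generator with
    kinship-structured liabilities for validation by simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    numDeriv,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
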