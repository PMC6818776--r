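Package: dyadseq
Title: Lag-Sequential Analysis of Micro-Coded Dyadic Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing interval-coded (micro-coded) dyadic
    interaction data. Computes per-dyad relative frequencies of binary
    behaviour categories and chance-corrected lag-1 sequencing likelihoods
    (a normalized Jaccard index), aggregates them across a sample with
    upper-tailed t-tests, Spearman and partial Spearman correlations with
    dyad-level covariates, leave-one-out outlier screening, and pooled
    Cohen's kappa for inter-rater reliability. Ships a seeded generator of
    coupled binary behaviour streams with linked covariates for validation
    and power exploration, and renders sample-average and correlation
    networks to DOT and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
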