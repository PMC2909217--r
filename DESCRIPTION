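Package: sgipred
Title: Predicting Synthetic Genetic Interactions from Weighted Functional Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted functional gene network by integrating
    protein-protein interactions, protein complexes and gene expression
    profiles, extracts weighted and binary topological features for gene
    pairs, and scores candidate pairs for synthetic genetic interaction
    with a graph-based semi-supervised (label propagation) classifier.
    Includes a supervised support-vector-machine baseline, a balanced
    cross-validation and ROC evaluation harness, per-feature two-sample
    Kolmogorov-Smirnov analysis, and a seeded synthetic-data generator
    that emulates modular co-expression, sparse modular interaction
    graphs, complexes and topology-correlated interaction labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
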