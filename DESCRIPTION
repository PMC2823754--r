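Package: hme3m
Title: Supervised Markov Mixture of Experts for Metabolic Pathway
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies frequently traversed paths through a known directed
    metabolic network that discriminate a binary biological response.  A
    mixture of first-order Markov chains over start-to-end network paths
    acts as the gating model of a two-layer hierarchical mixture of
    experts; each expert is a ridge-penalized logistic regression fitted
    by damped iteratively reweighted ridge regression.  Includes
    extraction of binary pathway observations from gene-expression data,
    exhaustive simple-path enumeration, a layered-network simulation
    benchmark with planted dominant paths, cross-validation and baseline
    comparisons (penalized logistic regression and support vector
    machines), ROC/AUC diagnostics, and GraphML/DOT export of fitted
    transition probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
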