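Package: lmpairnet
Title: Network-Based Prediction of Disease Associations for
    lncRNA-miRNA Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between diseases and lncRNA-miRNA
    pairs from three experimentally supported association catalogues
    (lncRNA-disease, miRNA-disease, lncRNA-miRNA). A triangle-filtered
    tripartite network is collapsed into a bipartite disease-pair
    network; diseases are compared by hierarchy-based semantic
    similarity and a Gaussian interaction-profile kernel, genes by
    best-match-average functional similarity plus the same kernel, and
    candidate links are scored with a truncated KATZ walk measure on the
    integrated block matrix. Includes leave-one-out and repeated k-fold
    cross-validation with ROC/AUC summaries, and a seeded synthetic-data
    generator with planted community structure for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
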