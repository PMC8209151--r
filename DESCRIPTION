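Package: mdlink
Title: miRNA-Disease Association Prediction from Heterogeneous Molecular
    Association Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by fusing
    attribute features (chaos-game-representation descriptors of miRNA
    sequences and MeSH-based disease semantic similarity) with behaviour
    features (structural deep network embeddings of a five-node-type
    molecular association network) and classifying pairs with a small
    one-dimensional convolutional neural network. Includes
    leakage-controlled five-fold cross validation, per-disease candidate
    ranking, a registry of baseline classifiers, and seeded synthetic
    fixture generators with planted block structure so the whole pipeline
    is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    randomForest,
    e1071,
    rpart,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
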