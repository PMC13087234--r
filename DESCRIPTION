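Package: fedcep
Title: Federated Clinical Event Prediction with Privacy-Preserving
    Gradient Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale simulator for blockchain-audited federated
    clinical event prediction from tabular electronic health records.
    Local hospital nodes preprocess EHR tables (neighbour-mean
    imputation, one-hot encoding, min-max normalization), derive
    temporal-causal-graph features from lagged correlations, and train a
    mean-centered graph neural network. Gradients are compressed by
    robust log scaling, protected by additively homomorphic masking, and
    signed with an exponential-probing hash. A global server
    authenticates submissions, clusters them with
    Calinski-Harabasz-initialized k-means under a Huber/cosine distance,
    aggregates per cluster, and redistributes updates blended by a
    polynomial-decay experience-replay rule. Every step is recorded on a
    tamper-evident hash-chained ledger. Includes synthetic cohort and
    time-series generators, continual-learning and classification
    metrics, and an end-to-end seeded simulation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
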