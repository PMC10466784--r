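Package: ldaEnsemble
Title: Predicting lncRNA-Disease Associations with a Graph Encoder and a
    Soft-Voting Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts lncRNA-disease associations from a sparse bipartite
    association network. Builds fused lncRNA and disease similarity matrices
    from Gaussian interaction-profile kernels, DAG-based disease semantic
    similarity and best-match-average lncRNA functional similarity; learns
    node embeddings with a stacked GCN-GAT-GCN graph encoder whose layer
    outputs are combined by a one-dimensional convolution and trained against
    the association matrix with a binary cross-entropy preference-matrix
    loss; and classifies concatenated pair embeddings with a soft-voting
    ensemble of a feed-forward neural network and second-order
    gradient-boosted regression trees. Includes negative sampling, the
    lncRNA-wise, disease-wise and pair-wise cross-validation protocols,
    rank-based evaluation metrics, and a seeded synthetic-data generator
    with planted low-rank structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
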