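Package: circMiRCAE
Title: Sequence- and Network-Based Prediction of circRNA-miRNA Associations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-miRNA associations from a bipartite interaction
    network and the RNA sequences themselves. Sequence "attribute" features are
    learned with k-mer Skip-Gram embeddings whose per-pair outer-product signal
    is compressed by a tied-weight convolutional autoencoder; network "behavior"
    features are PV-DM paragraph vectors over per-node interaction documents.
    Both streams are fused in a supervised deep classifier and evaluated with a
    stratified 5-fold cross-validation harness (specificity, precision,
    sensitivity, accuracy, Matthews correlation, AUC, AUPR). Includes PCA and
    raw k-mer frequency baselines, a planted-signal synthetic data generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    e1071,
    randomForest,
    xgboost,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
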