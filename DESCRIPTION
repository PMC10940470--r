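Package: ldaboost
Title: Boosted Link Prediction for lncRNA-Disease Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts long non-coding RNA (lncRNA)-disease associations from a
    sparse bipartite association matrix. Pair features are extracted by
    truncated singular value decomposition of the binary incidence matrix and
    classified by a convex fusion of two boosted learners: a transfer-learning
    SAMME.R AdaBoost ensemble of small one-dimensional convolutional networks,
    and a gradient-boosted decision-tree head. Includes three cold-start
    cross-validation protocols (held-out lncRNAs, held-out diseases, held-out
    pairs), six ranking and classification metrics, an ablation harness over
    the fusion weight, top-k candidate ranking for a disease of interest, and
    a planted low-rank synthetic association generator so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
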