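Package: otexpand
Title: Target-Indication Expansion from Evidence Scores, Target
    Similarity and Positive-Unlabeled Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts novel therapeutic indications for drug targets by
    combining Open-Targets-style association evidence with encoded
    target-disease features. Target-target similarity is derived from
    expression tissue specificity, Wang graph-based Gene Ontology
    semantic similarity, and node2vec embeddings of a protein-protein
    interaction network; a collaborative-filtering equation turns each
    similarity source into a new target-disease feature as the
    similarity-weighted average of the top-k most similar targets'
    known-drug scores, with leakage-safe masking of held-out targets.
    Positive-unlabeled classifiers (bagged logistic regression, random
    forest, XGBoost) are trained under target-level train/test splits
    and grouped cross-validation, and evaluated with precision-recall
    machinery, F-beta threshold selection, agreement statistics,
    group-wise AUPR, permutation importance, indication ranking and a
    hypergeometric overlap test. A synthetic-data generator with
    planted module structure emulates every input so the full pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
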