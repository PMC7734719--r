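Package: kgwalc
Title: Discriminative Wildcard-Walk Mining for Node Classification in
    Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines fixed-depth wildcard walks (root -> * -> ... -> label)
    that maximize information gain for a node classification task on a
    knowledge graph. Triples are converted to a label-only directed graph
    in which each triple contributes a per-occurrence predicate vertex;
    per-entity depth-indexed neighborhood label sets make walk containment
    a constant-time set-membership test. Three interpretable classifier
    constructions are provided on top of the miner: a decision tree whose
    internal nodes test walk presence, a bootstrap/candidate-sampled
    forest with walk importances, and a single-pass top-K feature
    transform producing binary walk-presence matrices for downstream
    classifiers. Includes N-Triples/Turtle readers, deterministic
    synthetic graph generators with planted discriminative walks, DOT
    export of trees, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
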