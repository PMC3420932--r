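Package: pathshortcuts
Title: Pathway-Consistent Prediction of Missing Edges in Weighted
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts missing edges in confidence-weighted, directed
    protein interaction networks so that a signaling pathway's sources
    (sensors) and targets (transcription factors) become better connected.
    Implements a greedy algorithm that repeatedly adds the candidate edge
    giving the largest reduction in total source-to-target shortest-path
    cost, in four variants (all pairs or single closest source, with or
    without a hop restriction enforced by a bounded Bellman-Ford kernel),
    using constant-time incremental candidate evaluation from precomputed
    forward and reverse distance tables. Also provides four baseline
    predictors (direct source-target, source-target edge betweenness,
    weighted Jaccard common-neighbor scoring, and closest non-interacting
    pair), an evaluation suite (cost-reduction curves, accuracy against
    reference edge sets, held-out-edge cross-validation, hypergeometric
    overlap enrichment), and a generator of layered synthetic pathway
    networks with planted hidden shortcut edges for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
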