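Package: mtgraph
Title: Multi-Task Representation Learning for Graph and Node Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint supervised graph classification and node classification on
    collections of small labeled graphs (molecules, proteins) via hard
    parameter sharing. Implements a multi-task Graph Isomorphism Network
    (MT-GIN: sum aggregation, per-layer readout concatenation) and a
    multi-task differentiable-pooling model (MT-DIFFPOOL: GraphSAGE mean
    aggregation, soft cluster assignment, pre-pool node head), a combined
    loss L_G + alpha * L_v, a reader/writer for the TU Dortmund benchmark
    format, a synthetic labeled-graph generator with a controllable
    node-label/graph-label coupling, Adam training with stratified k-fold
    cross-validation, and 2-D embedding visualization via t-SNE. Training is
    backed by a small built-in reverse-mode automatic differentiation tape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
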