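Package: stimflow
Title: Response Pseudotime and Temporal Decomposition for Post-Stimulation Single-Cell Time Series
Version: 0.1.0
Authors@R: person("stimflow", "maintainers", email = "maintainers@stimflow.dev", role = c("aut", "cre"))
Description: Toolkit for analysing single-cell RNA-seq time courses collected
    after an acute perturbation (e.g. interferon-alpha stimulation of
    hematopoietic stem and progenitor cells). Provides control-anchored cell
    type annotation via Leiden clustering and k-nearest-neighbour label
    transfer, response-gene selection from per-cluster differential
    expression, a change-score/similarity-score decomposition of global
    versus cluster-specific expression dynamics, a semi-supervised response
    pseudotime obtained by closed-form least-squares regression of
    standardized expression onto experimental time labels, pseudotemporal
    pattern clustering, bootstrap/LOESS profile smoothing, and a
    sigmoid-dynamics time-series simulator with known ground truth used to
    validate pseudotime recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
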