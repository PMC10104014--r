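Package: embryotree
Title: Cell-Type Graph Inference and Temporal Analysis for Whole-Embryo
    Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing developmental cell-type relationships
    from time-series single-cell RNA-seq atlases of embryogenesis. Implements
    simulated-doublet kNN scoring with two rounds of subcluster-level doublet
    flagging, mutual-nearest-neighbor (MNN) based cell-type graph construction
    with normalized edge scores and time-resolved edge profiles, four-phase
    stratification of cell-type transitions with phase-resolved nomination of
    differentially expressed transcription factors, timepoint k-NN purity and
    correlation statistics for detecting abrupt transcriptional shifts (such
    as those occurring at birth), cubic growth-curve modeling of whole-embryo
    cell number, principal-component/feature correlation with a
    mean-plus-minus-one-SD significance rule, and cross-compartment sign
    concordance tests. A seeded synthetic embryo-series generator with known
    lineage ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
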