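Package: slidecms
Title: Tile-Based Prediction of Consensus Molecular Subtypes from H&E Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a three-stage pipeline for
    predicting the consensus molecular subtypes (CMS1-4) of colorectal
    cancer from haematoxylin-and-eosin slide images: annotation-restricted
    overlapping tiling, a tile-level four-class probability scorer trained
    with patient-level stratified five-fold splits, slide-level probability
    aggregation with five-model majority-vote ensembling (including the
    "mixed" outcome), a virtual-biopsy sampling simulator that measures
    classification performance as a function of the number of biopsy
    fragments, macro one-vs-rest AUROC evaluation, and covariate-adjusted
    odds-ratio analysis of subtype versus pathological complete response.
    Ships a seeded synthetic-cohort generator (textured pseudo-slides,
    polygon annotations, biopsy fragment shape libraries, outcome tables)
    so the whole pipeline is testable end to end without any slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    polyclip,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    mgcv,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
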