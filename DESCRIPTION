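Package: subnetip
Title: Literature-Augmented Subnetwork Inference with Integer Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers molecular subnetworks that connect experimentally
    identified source genes (e.g. RNAi screen hits) to target entities
    (viral components, differentially expressed genes) through a typed,
    partially-directed background network. Candidate source-to-target
    paths are enumerated to a bounded depth and a subset is selected by
    lexicographic (sequential) integer programming, solved with an exact
    implicit-enumeration branch-and-bound. Robustness is assessed with
    subsample ensembles, consensus subnetworks, and hold-aside
    precision-recall evaluation. Literature-derived evidence augments the
    analysis by ranking genes against a query corpus with an
    adjusted-precision/recall F1, promoting well-supported genes to
    sources, importing text-mined regulatory interactions as edges, and
    extracting concept-focused "views" of an inferred subnetwork by
    path-overlap similarity. A synthetic-data module generates planted
    benchmark networks, matched literature corpora and expression tables
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
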