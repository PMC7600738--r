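Package: map4np
Title: MinHashed Atom-Pair Fingerprints, Chemical Space Maps and Origin
    Classification for Microbial Natural Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyze collections of microbial natural products from SMILES
    tables: MinHashed atom-pair (MAP4-style) fingerprints with an
    estimated-Jaccard similarity, locality-sensitive-hashing forest
    nearest-neighbor search, minimum-spanning-tree chemical space maps,
    physico-chemical and substructure annotation (including a Joback
    group-contribution boiling point and Lipinski flagging), and kernel
    support-vector-machine and k-nearest-neighbor classifiers that assign a
    bacterial or fungal origin to a structure. Includes a fragment-grammar
    generator of synthetic molecule sets with controllable class signal for
    download-free testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    openssl,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
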