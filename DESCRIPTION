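Package: poolscreen
Title: Fitness Analysis of Pooled Deletion-Collection Chemogenomic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled barcode (TAG) microarray fitness
    screens of the yeast deletion collection: faster-cyclic-loess (fastlo)
    normalization of chip signals with UP/DOWN barcodes treated as separate
    measurements, differential strain sensitivity analysis (DSSA) with
    q-value significance and cross-treatment consensus filtering, gene-wise
    mixed-effects dose models with likelihood-ratio tests and Holm
    correction, Kruskal-Wallis gene statistics feeding a graph-aware
    permutation pathway enrichment test, degree-aware sub-network enrichment
    on scored protein-interaction networks, hypergeometric functional
    category enrichment, and growth-curve AUC/ICx dose-response summaries.
    Ships a synthetic-data generator that emulates the screen design with
    planted ground truth, for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    nlme,
    optparse
Config/testthat/edition: 3
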