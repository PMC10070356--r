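Package: enlink
Title: Cell Type-Specific Scoring of Cis Enhancer-Gene Regulatory Links
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Machine-learning scoring of cis enhancer-gene pairs (enhancer
    within 1 Mb of a gene's transcription start site) for the likelihood of
    an active regulatory relationship. Assembles labeled training sets from
    literature-curated positive links and DNA-accessibility-derived negative
    pairs, engineers epigenomic (H3K27ac, H3K4me1, H3K4me3, P300) and
    cis-eQTL features with interaction terms, trains a registry of
    probabilistic classifiers, selects a final model by cross-cell-type
    precision-recall performance, and normalizes genome-wide scores per cell
    type into Z-scores and percentile F(scores). Ships a fully synthetic
    regulatory-genome simulator so every pipeline stage is testable without
    external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    kernlab,
    glmnet,
    randomForest,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    withr,
    optparse
Config/testthat/edition: 3
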