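Package: dkppi
Title: Protein-Protein Interaction Extraction with Dominant-Keyword Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts protein-protein interactions (PPI) from annotated
    sentences by classifying protein-pair instances with a 44-dimensional
    feature encoding (lexical, constituent-parse, and pattern features),
    partitioning the training set four ways by dominant-keyword status and
    keyword position, and refining per-instance dominant-keyword flags with
    an iterative two-classifier cross-validation loop. Includes readers for
    the unified PPI XML interchange format and bracketed parse trees, a
    random-forest model pipeline with five method variants, a
    cross-validated evaluation harness, and a synthetic-corpus generator
    with planted dominant-keyword ground truth.
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
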