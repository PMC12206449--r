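Package: methtransfer
Title: Transfer Learning for Multi-Cancer Classification from Cell-Free DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-class cancer classification from cell-free DNA
    (cfDNA) methylation profiles. Implements beta-value preprocessing with
    detection-P quality control and strict missingness filtering, fusion of
    methylation beta values with reduced DNA-sequence embeddings of probe
    flanking windows, a bottleneck residual network trained with Adam and
    early stopping, two-phase transfer learning with block freezing, an
    OpenMax open-set layer with per-class Weibull tail calibration for
    unknown-cancer detection, weighted multi-class evaluation metrics with
    stratified cross-validation and a leave-one-class-out unknown-masking
    protocol, gradient-based probe attribution with probe-to-gene mapping,
    and synthetic cohort generators so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    fitdistrplus,
    knitr,
    rmarkdown
Config/testthat/edition: 3
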