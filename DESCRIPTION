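Package: repopsig
Title: Reversal of Aging Expression Signatures After Forced Microglial
    Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for deciding whether forced microglial turnover
    (CSF1R-antagonist depletion followed by repopulation) reverses the
    aging transcriptional signature. Implements median-of-ratios
    normalization, per-gene negative-binomial Wald contrast tests with
    Benjamini-Hochberg false-discovery-rate control, the age-signature
    definition, the four-way Reversed / Partially Reversed / Exacerbated /
    Unaffected reversal taxonomy, the LPS-response taxonomy for
    inflammation panels, and comparative-CT (delta-delta-CT) qPCR fold
    changes. A factorial negative-binomial count simulator plants
    recoverable per-gene category structure so every stage of the
    inference chain is verifiable by parameter recovery at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
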