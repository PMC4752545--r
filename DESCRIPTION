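Package: crossfroc
Title: Crossed-Modality JAFROC Analysis for Free-Response Observer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing free-response (FROC) observer studies in
    which the imaging condition is defined by two fully crossed factors,
    such as tube current-time product (mAs) crossed with image
    reconstruction method. Computes the equally weighted JAFROC (wAFROC)
    figure of merit and the highest-rating inferred-ROC figure of merit,
    performs Obuchowski-Rockette analysis with Hillis modifications
    (random-reader fixed-case and random-reader random-case) using
    jackknife covariance estimation, and implements the crossed-modality
    procedure: two sequential single-factor analyses on factor-averaged
    figures of merit with Bonferroni protection. Includes scoring of raw
    observer marks against a lesion truth table with an acceptance radius,
    a search-model rating simulator for type-I error and power validation,
    an anthropomorphic thorax phantom truth fixture, and ancillary image
    quality and dosimetry metrics (contrast-to-noise ratio trend analysis,
    ICRP 103 effective dose).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
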