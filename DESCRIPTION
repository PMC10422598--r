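Package: soyemerge
Title: Seedling Emergence Detection and Growth-Stage Evaluation from Nadir
    RGB Field Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble pipeline for evaluating crop seedling emergence from
    nadir RGB field images, developed around row-planted soybean. Seedlings are
    counted by adaptive (Otsu) thresholding of a vegetation index followed by
    8-connected component analysis; each detection is cut into a labelled
    255x255 crop; crops are classified into early growth stages (VE, VC, V1)
    with a compact AlexNet-style convolutional network implemented in
    'RcppArmadillo'; per-stage emergence proportions and an emergence
    uniformity verdict are reported, together with count-agreement statistics
    (R-squared, RMSE, MAE, average accuracy) against manual counts. A
    synthetic field-scene generator with exact ground truth makes every stage
    of the pipeline testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
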