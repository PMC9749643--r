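Package: morphopotency
Title: Morphology-Based Prediction of Stem Cell Multipotency from
    Two-Channel Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for estimating the
    multipotency of mesenchymal-like stem cell populations from two-channel
    single-cell fluorescence images: a synthetic cohort generator with planted
    per-donor multipotency fractions and shape-potency coupling, selective-search
    and threshold-based single-cell detection, marker-intensity labelling,
    eigenshape (contour PCA + K-means) shape-mode morphometry, a small
    convolutional neural network classifier trained with Adam and early
    stopping, Gaussian-process Bayesian optimization of the learning rate with
    the expected-improvement acquisition, stratified cross-validated evaluation,
    and per-donor multipotency-ratio estimation with bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
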