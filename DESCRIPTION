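Package: rgbentropy
Title: Multivariate Sample and Fuzzy Entropy for Multichannel Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bi-dimensional multivariate sample entropy and multivariate
    fuzzy entropy for multichannel (e.g. RGB) raster images, with a
    multiscale extension based on block-mean coarse-graining. Includes the
    MIX family of controlled-irregularity synthetic image and signal
    generators used to validate the measures, preprocessing utilities
    (center crop, z-normalization, grayscale conversion), and an SVM-based
    texture-classification harness that turns multiscale entropy profiles
    into feature vectors and reports accuracy over repeated stratified
    train/test splits. The entropy kernels are implemented in C++ for
    speed, with naive reference implementations retained for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
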