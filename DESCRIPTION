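Package: seedspec
Title: Full-Band Hyperspectral Seed Variety Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying seed varieties from
    hyperspectral reflectance spectra. Reads and writes ENVI-style image
    cubes, performs dark/white reflectance calibration, extracts per-seed
    mean spectra from rectangular regions of interest, and applies standard
    chemometric smoothing (Savitzky-Golay, Gaussian, median, moving
    average) and Savitzky-Golay derivatives. Classifiers include k-nearest
    neighbours with configurable transforms and distances (including
    shrinkage Mahalanobis), an extreme learning machine solved in closed
    form, and a family of one-dimensional convolutional networks with an
    optional squeeze-and-excitation channel-attention block, trained with
    Adam on the cross-entropy loss via a compiled single-precision backend.
    A synthetic-spectra generator emulates multi-variety seed trays so the
    whole pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
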