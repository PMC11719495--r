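Package: scalonet
Title: Scalogram-Tiling Depthwise Convolutional Networks for EEG Seizure
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 35-channel, 1-second EEG segments as epileptic or
    normal by rendering each channel's continuous wavelet transform (real
    Morlet) as a jet-colormapped 100x100 scalogram image, tiling the 35
    images into a single 500x700 composite on a 7x5 grid, and training a
    compact depthwise convolutional neural network on the composites.
    Includes a synthetic spike-and-wave EEG generator for end-to-end
    testing, shape/parameter accounting for the network architecture, a
    confusion-matrix evaluation suite (accuracy, sensitivity, specificity,
    precision, F1), and a command-line pipeline covering simulation,
    scalogram rendering, tiling, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
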