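Package: melpcg
Title: Mel and Log-Mel Spectrogram Features for Domain-Robust
    Heart-Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying phonocardiogram (heart-sound)
    recordings as normal or abnormal from short-time Fourier transform
    based MelSpectrum and Log-MelSpectrum feature maps. Implements the
    full pipeline: WAV input, Butterworth band-limiting and
    Savitzky-Golay smoothing, fixed-length segmentation, triangular Mel
    filterbank features, a compact VGG-style convolutional classifier
    trained with Adam and Kaiming initialisation, and a
    leave-one-domain-out evaluation protocol with sensitivity,
    specificity and mean-accuracy reporting. A seeded acquisition
    simulator models a recording as the heart source plus additive
    background noise convolved with a stethoscope impulse response, and
    generates multi-domain datasets with per-domain channel coloration
    and class imbalance, so that the additive-shift property of log-Mel
    features under channel (multiplicative) effects can be studied at
    desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
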