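Package: fecgdenoise
Title: Multi-Channel Fetal ECG Denoising with a Convolutional Encoder-Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing noisy multi-channel fetal electrocardiograms
    after maternal ECG suppression. Provides a synthetic fetal ECG simulator
    (Gaussian-sum vectorcardiogram beats with randomized PQRST morphology,
    rhythm variability and SNR-calibrated composite noise), a deep 1D
    convolutional encoder-decoder denoiser with symmetric additive skip
    connections trained with a normalized mean squared error loss, classical
    wavelet-thresholding and beat-averaging reference denoisers with a
    Pan-Tompkins QRS detector, and a quantitative evaluation protocol based on
    SNR improvement, running-median surrogate references and windowed
    least-squares scalp-lead estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
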