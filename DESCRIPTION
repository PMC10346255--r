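Package: emgsign
Title: Surface EMG Sign-Language Gesture Recognition with Dilated
    Residual Inception Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognising sign-language gestures from
    multichannel surface electromyography (sEMG). Provides Butterworth
    bandpass and mains-notch preprocessing, muscle-activity onset
    detection by short-term energy and variance thresholds on the
    channel-mean signal, sliding-window discrete Fourier transformation
    into time-frequency tensors, a parallel 1-D convolutional network
    combining Inception-style multi-kernel branches with residual
    shortcuts and dilated convolutions (including its ablation
    variants), a geometric receptive-field calculator, a
    protocol-structured synthetic sEMG generator with ground-truth
    annotations, and a stratified train/validation/test evaluation
    harness with per-class metrics and confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
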