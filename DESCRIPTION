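Package: merstn
Title: Microelectrode-Recording Analysis for Intraoperative Subthalamic Nucleus Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing the subthalamic nucleus (STN) from depth-ordered
    microelectrode recordings (MER) acquired during deep-brain-stimulation surgery.
    Provides a synthetic MER simulator (Poisson multi-unit spiking on filtered
    background noise with the clinical depth schedule), acquisition-chain filtering,
    amplitude-threshold spike detection, three per-epoch feature spaces (ten
    conventional spike-train and signal statistics with per-trajectory
    normalization, binned FFT power spectra, and Haar discrete-wavelet
    coefficients), classical classifiers with a weighted-majority-vote ensemble,
    a deep feed-forward network with L2 and dropout regularization, evaluation
    via held-out splits and stratified ten-fold cross-validation, and conversion
    of per-depth predictions into dorsal/ventral STN border estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
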