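Package: forceskill
Title: Surgical Skill Classification from Tool-Tissue Force Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark toolkit for force-based surgical skill classification
    (FSC): labeling a microsurgical trial as performed by an Expert or a Novice
    surgeon from the univariate tool-tissue force trace recorded during the
    trial. Provides preprocessing (negative-force clipping, standard scaling,
    random 300-step cropping with zero padding), a seeded synthetic
    expert/novice cohort generator, six time-series data augmentations (real
    FFT channel stacking, quantization, drift, time warp, Gaussian noise,
    temporal jittering), six sequence-classification architectures (LSTM,
    Bi-LSTM, GRU, CLDNN, TCN, Transformer) with a built-in training engine,
    two cross-validation protocols (random six-fold and leave-one-user-out),
    confusion-matrix metrics with per-fold reporting, and temporal saliency
    overlays that visualize where a trained network attends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
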