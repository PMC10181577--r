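Package: aewear
Title: Joint-Wear Diagnostics from Acoustic-Emission Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying joint-wear pathologies from single-channel
    acoustic-emission (AE) recordings. Provides a seeded generator of five
    classes of wear-signature burst signals (abrasive, adhesive, burnishing,
    burnishing-to-scratching, scratching) rendered through a resonant-sensor
    instrument model, disjoint windowing, a bank of sixteen handcrafted
    time/frequency/complexity/fractal features, a two-order deep wavelet
    scattering transform with Gabor filter banks, a benchmark harness over
    twelve classical classifiers with stratified hold-out and 10-fold
    cross-validation, ReliefF feature ranking, and a reproducible end-to-end
    experiment driver with tidy outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
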