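Package: stereocorr
Title: Local Cross-Correlation Model of Spatial Stereoresolution with a
    Size/Disparity Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates human spatial stereoresolution for random-dot depth
    corrugations with a population of windowed normalized cross-correlators
    whose Gaussian window size grows with preferred disparity (a
    size/disparity correlation). Provides random-dot stereogram synthesis for
    sine-wave and square-wave disparity gratings and matched disparity-noise
    patterns, eye-optics preprocessing (point-spread blur and rescaling),
    the correlator population response, a template-matching ideal-observer
    decision stage, two-interval forced-choice psychometric simulation with
    upper depth-limit (disparity-gradient) analysis, and a numerical
    demonstration that the windowed correlator equals a bank of binocular
    energy units summed over spatial frequency and orientation.
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
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
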