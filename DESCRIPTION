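Package: reflexgait
Title: Spinal Reflex Control Model of Human Walking and Gait-Disturbance Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sagittal-plane neuromechanical simulation of human walking driven by
    delayed proprioceptive spinal reflexes, with Hill-type muscle-tendon actuators
    and compliant (split-belt capable) ground contact. Implements five classic
    gait-disturbance protocols (afferent stimulation pulses, tendon taps, imposed
    ankle stretch, swing-leg tripping against an obstacle, and stance-side surface
    slips), response-trend extraction and band-overlap similarity statistics for
    comparing model reactions with electromyographic reference data, a synthetic
    reference-data generator with known ground truth, and metabolic-cost-based
    optimization of the reflex parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    arrow,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
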