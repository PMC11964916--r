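Package: hrsnn
Title: Spiking Neural Networks for Multi-Scale Heart-Rate Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating an always-on, neuromorphic heart-rate
    monitoring pipeline. Generates synthetic photoplethysmography (PPG)
    waveforms with controlled heart-rate trajectories and calibrated
    white or colored noise; converts waveforms to spike trains through a
    Butterworth band-pass filter bank, full-wave rectification and leaky
    integrate-and-fire (LIF) encoding; simulates recurrent spiking
    networks (soft winner-take-all and neural state machines) that decode
    instantaneous heart rate and track heart-rate zones and monotonic
    trends; removes motion artifacts by Nelder-Mead optimization of a
    linear PPG/accelerometer channel combination against ECG-derived
    firing rates; and estimates the power and energy consumption of the
    equivalent mixed-signal neuromorphic hardware from per-operation
    energy costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
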