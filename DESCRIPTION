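Package: prcnoise
Title: Phase-Resetting-Curve Estimation and Spike-Time Prediction from
    Injected Current Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repetitively firing neurons densely perturbed
    by pulsed Gaussian current noise. Simulates stochastic phase oscillators
    (single trajectories and Monte Carlo ensembles), estimates the infinitesimal
    phase-resetting curve (PRC) from a perturbed spike train by multiple linear
    regression on per-phase-bin charge with interpolated-phase or mean-period
    binning, predicts spike times and interspike-interval variability from the
    PRC, and evaluates a closed-form approximation for the coefficient of
    variation of interspike intervals under pulsed noise. Includes a synthetic
    experiment generator emulating perforated-patch recordings of autonomously
    firing neurons, plus delimited-text readers and writers for current and
    voltage traces, spike trains, and tabulated PRCs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
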