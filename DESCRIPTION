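Package: echoclass
Title: Entropy-Optimized Reservoir Computers for Chaotic Signal Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates reservoir computers built from spiking-neuron or
    polynomial ordinary-differential-equation nodes, drives them with the
    x components of the Sprott A-D chaotic flows (optionally encoded as
    spike trains), and trains linear readouts by singular-value ridge
    regression.  Signals are classified by the Euclidean distance between
    readout coefficient vectors fitted on training and test realizations.
    Provides joint permutation entropy and nearest-neighbor entropy
    estimators for the reservoir state, Gram-Schmidt Lyapunov spectra for
    the autonomous drive systems and conditional exponents for the driven
    reservoir, and a one-parameter sweep harness showing that
    hyperparameters maximizing reservoir entropy minimize classification
    error.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
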