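Package: fretflow
Title: Single-Molecule FRET and Flow-Extension Analysis of Protein-ssDNA Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single-molecule measurements of protein binding
    to single-stranded DNA. Corrects donor/acceptor smFRET intensity traces,
    segments FRET time series into discrete states with a Gaussian-emission
    hidden Markov model selected by BIC, extracts censored dwell times,
    estimates association and dissociation rate constants by exponential
    fitting, and derives the dissociation constant from a rate titration as
    the concentration where the concentration-proportional on-rate crosses
    the concentration-independent off-rate. A companion arm analyses
    tethered-bead flow-extension trajectories: exponential-rise extension
    fits, hyperbolic concentration saturation, washout decay, and
    equipartition force calibration from transverse bead fluctuations.
    A synthetic-data module generates ground-truth traces and bead
    trajectories so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
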