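Package: gradnet
Title: Nonlinear Gradient-System Modeling and Trajectory Correction for
    Non-Cartesian MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the temporal response of an MRI gradient chain and
    propagates predicted gradient waveforms through non-Cartesian image
    reconstruction and diffusion tensor mapping. Provides a waveform
    library generator (trapezoids, triangle trains, slew-constrained
    chirps, multisines, spiral-in-out and rosette readouts), a synthetic
    nonlinear gradient-system simulator (band-limited delayed linear core
    with eddy-current terms, zero-crossing crossover distortion,
    amplitude-dependent gain and delay, slew-rate limiting, measurement
    noise), a linear gradient impulse response function (GIRF) estimator,
    a temporal convolutional network and LSTM trained to predict played-out
    waveforms from nominal ones, k-space trajectory integration and error
    metrics, density-compensated Kaiser-Bessel gridding reconstruction with
    time-segmented off-resonance correction, and weighted linear least
    squares diffusion tensor fitting with MD/FA/RD/AD maps and
    cross-reconstruction parameter correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    Matrix,
    Rcpp,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
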