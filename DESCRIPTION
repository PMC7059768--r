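Package: memdeeg
Title: Multivariate Empirical Mode Decomposition for Low-Density EEG
    Source Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-frequency preprocessing of multichannel EEG with
    empirical mode decomposition (EMD) and its multivariate extension
    (MEMD), entropy-based selection of intrinsic mode functions,
    synthetic EEG generation from a three-shell spherical head model
    with windowed-sinusoid cortical sources, Bayesian source
    reconstruction with multiple sparse priors (MSP) and a minimum-norm
    baseline, and spatial accuracy assessment of source reconstructions
    with the earth mover's (1-Wasserstein) distance.  Supports
    channel-reduction studies on 10-10 system montages of 32, 16 and 8
    electrodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
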