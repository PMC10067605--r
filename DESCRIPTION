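Package: flexreach
Title: Goal-Directed Reaching Through Active Inference with Flexible Intentions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a continuous-time active inference agent that controls a
    planar three-joint limb to reach and track visual targets. Beliefs over arm,
    target and home postures evolve in generalized coordinates under
    precision-weighted proprioceptive and visual prediction errors, while
    flexible intention functions inject dynamic attractors into the belief
    dynamics. Includes the simulated body and visual world, a differentiable
    soft rasterizer and a convolutional variational-autoencoder visual model
    with exact reverse-mode pullbacks, the delayed-reaching, movement-onset and
    target-tracking experiment drivers, performance metrics with confidence
    intervals, and precision-sweep and gradient-field analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    withr
Config/testthat/edition: 3
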