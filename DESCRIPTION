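Package: ucpwi
Title: Deep-Learning Post-Processing for Ultrasound Contrast-Agent
    Plane-Wave Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Three-stage post-processing of plane-wave ultrasound
    contrast-agent channel data: a 1-D U-net (with CNN and RNN baselines)
    that classifies radio-frequency signal segments as microbubble or
    tissue, a bubble-approximated wavelet transform whose mother wavelet
    is the scattered pressure of a shelled microbubble (Doinikov model)
    combined with a maximum-eigenvalue threshold, and eigenspace-based
    minimum-variance (ESBMV) beamforming.  Includes a plane-wave
    channel-RF simulator with per-sample ground-truth labels used for
    training and evaluation, and contrast-to-tissue / contrast-to-noise
    image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pROC,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
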