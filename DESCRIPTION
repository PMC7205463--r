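Package: popglm
Title: Coupled Poisson Population Encoding Models for Simultaneously
    Recorded Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits fully coupled Poisson generalized linear models to
    ensembles of simultaneously recorded spike trains from delayed-response
    tasks. Each neuron's conditional intensity is modeled with task-event
    kernels, a spike-history kernel, and interneuronal coupling kernels on
    nonlinearly time-scaled raised-cosine bases, estimated by ridge-penalized
    maximum a posteriori inference with trial-wise cross-validation. Includes
    permutation-null calibration of coupling, kernel summaries (weights,
    gains, principal components, double-exponential time constants),
    predictive indices, epoch-restricted fits, spatial-tuning relationships,
    synthetic-data generators with known ground truth, and a ring
    bump-attractor spiking network for relating estimated coupling to
    recurrent connection strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
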