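Package: streamlmm
Title: Streaming EM Estimation of Linear Mixed Models on Data Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Online (streaming) expectation-maximization estimation of linear
    multilevel models with an arbitrary number of correlated random effects.
    Each incoming data point triggers an E-step for the individual it belongs
    to, using per-individual sufficient statistics instead of raw data, and an
    immediate closed-form M-step with a Sherman-Morrison rank-one update of the
    fixed-effect normal equations. Includes the classical offline EM estimator,
    periodic full-sweep updates over stored individual summaries, a
    sliding-window EM comparator, a synthetic data-stream simulator, a
    prequential (predict-then-update) evaluation harness, stream readers and
    writers, checkpointing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    MASS,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
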