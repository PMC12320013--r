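Package: soccd
Title: Second-Order Causal Discovery for Autocorrelated Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Instantaneous (contemporaneous) causal direction estimation
    between temporally autocorrelated variables using only second-order
    statistics. Implements a Gaussian mutual-information / likelihood-ratio
    decision criterion computed from log-determinants of window covariance
    matrices, together with pairwise LiNGAM and bivariate Granger-causality
    baselines, a two-stage directed-network estimator (cross-validated
    graphical-lasso skeleton plus pairwise edge orientation), an
    autoregressive Monte-Carlo simulation benchmark, split-half reliability
    procedures, and amplitude-envelope preparation utilities for
    oscillatory signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
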