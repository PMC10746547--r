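Package: stabcal
Title: Stability Selection with Automated Calibration for Penalised
    Regression and Graphical Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stability selection for LASSO regression and Gaussian
    graphical models with joint calibration of the penalty parameter and
    the threshold in selection proportion by maximisation of a stability
    score, optional control of the per-family error rate (PFER) through
    closed-form upper bounds, a multi-block extension for heterogeneous
    (e.g. multi-OMIC) data using block penalty matrices with a weak
    penalty on off-target blocks, and a companion simulator of
    graphical-model and regression data with known ground truth. The
    graphical LASSO solver supports elementwise penalty matrices and is
    implemented by block coordinate descent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
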