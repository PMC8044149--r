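Package: boldcast
Title: Graph-Constrained Forecasting and Causal Connectivity for Regional
    Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-to-sequence forecasting of parcel-averaged brain
    activity on a structural connectivity graph using diffusion-convolutional
    gated recurrent units, with scheduled-sampling training, transfer
    learning across graphs, a vector-autoregression baseline with OLS and
    stochastic-gradient fits and an augmented Dickey-Fuller stationarity
    screen, a perturbation-based measure of directed (causal) connectivity,
    and a synthetic generator of graph-coupled band-limited signals with
    planted directed couplings for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
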