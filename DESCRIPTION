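Package: fluxmem
Title: Memory Effects of Climate and Vegetation on Forest Net Ecosystem Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how far back in time climate and
    vegetation states influence monthly net ecosystem CO2 exchange (NEE) at
    forest eddy-covariance sites. Provides a seeded generator of
    FLUXNET-like multi-site monthly panels whose NEE carries a controllable
    memory horizon through a lagged carbon pool; two-stage random-forest
    gap-filling of surface-reflectance bands and NSE-selected climate
    down-scaling; a single-layer LSTM sequence regressor with masked loss,
    hand-implemented backpropagation through time and Adam, trained as a
    multi-initialization ensemble; a factorial set of predictor ablations
    (temporal permutation, mean-seasonal-cycle and annual-mean vegetation,
    static random forest); entire-site k-fold cross-validation; a
    counterfactual altered-forcings experiment; and a four-scale evaluation
    decomposition (seasonal cycle, seasonal anomalies, interannual
    anomalies, across-site) with Nash-Sutcliffe efficiency and companion
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    kernlab,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
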