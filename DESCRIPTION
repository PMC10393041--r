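Package: hetercgm
Title: Multi-Patient Blood Glucose Forecasting on Heterogeneous CGM Records
Version: 0.1.0
Authors@R: person("CGM", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simultaneous multi-step blood glucose forecasting for cohorts of
    diabetic patients monitored by continuous glucose monitoring (CGM) sensors
    with unequal record lengths. Implements subsequence-repetition (SSR)
    alignment of heterogeneous series (with padding and truncation baselines),
    a sparse relation graph over patient samples built from dynamic time
    warping (DTW) distances, and the HETER network: stacked graph convolutions,
    a spatial convolution filter, temporal attention, a GRU recurrent
    component, and a linear residual output head. Includes a synthetic CGM
    cohort generator, Adam/MSE training with analytic gradients, MAE/MAPE/RMSE
    and Pearson-correlation evaluation, grid search, sensitivity sweeps, and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
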