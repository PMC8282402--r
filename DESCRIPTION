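Package: ecgarch
Title: Heteroskedastic Time-Series Modelling of Single-Lead ECG Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models one-minute single-lead ECG segments as the sum of a
    linear conditional-mean process (ARIMA) and a nonlinear conditional-variance
    process (ARCH, GARCH, GJR-GARCH or EGARCH), the decomposition used in
    sleep-apnea signal modelling. Provides from-scratch Gaussian quasi-maximum-
    likelihood estimation of the mean and volatility models and of the joint
    ARIMA-EGARCH composite, a heteroskedasticity diagnostic battery (moment
    summaries, Engle's ARCH-LM test, a tie-adjusted Wilcoxon signed-rank test,
    histogram/CDF comparison), per-observation normalised AIC/BIC order
    selection over candidate grids, MSE/RMSE/MAE/MAPE segment evaluation with
    per-label aggregation, and a synthetic generator of ECG-like
    volatility-clustered segments with known ground truth in apnea-like and
    normal-like regimes. Reads plain-CSV amplitude series and, optionally,
    PhysioNet WFDB records with per-minute apnea annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
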