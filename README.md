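# ecgarch

Heteroskedastic time-series modelling of single-lead ECG segments.

An ECG amplitude series has a mean *and* a variance that drift over time:
beats impose a quasi-periodic mean, and the noise around them arrives in
volatility clusters — calm stretches punctuated by bursts, a pattern that is
accentuated during obstructive sleep apnea. `ecgarch` models one-minute ECG
segments (6000 samples at 100 Hz) as the sum of a linear conditional-mean
process and a nonlinear conditional-variance process:

* **mean**: ARIMA(p, d, q), `(1 - sum a_k L^k)(1 - L)^d X_t = (1 + sum b_k L^k) eps_t`;
* **variance**: ARCH / GARCH / GJR-GARCH / EGARCH on the innovations,
  `eps_t = sigma_t Z_t`, `Z_t ~ N(0,1)` — e.g. EGARCH's
  `log sigma_t^2 = alpha_0 + sum beta_k' g(Z_{t-k}) + sum alpha_k' log sigma_{t-k}^2`
  with `g(Z) = theta Z + lambda (|Z| - sqrt(2/pi))`;
* **composite**: ARIMA-EGARCH with jointly refined mean and variance
  parameters, the configuration that models apneic and normal segments best.

The package is aimed at biosignal researchers who want the full pipeline on
their own recordings or on synthetic ground truth: heteroskedasticity
diagnostics (moment summaries, Engle's ARCH-LM test, a tie-adjusted Wilcoxon
signed-rank test, histogram/CDF comparison), from-scratch Gaussian
quasi-maximum-likelihood estimation of every model family, normalised
AIC/BIC order selection over candidate grids, MSE/RMSE/MAE/MAPE evaluation
with per-label aggregation, a synthetic generator of ECG-like segments in
"apnea-like" and "normal-like" regimes with known truth, plain-CSV and
(optionally) PhysioNet WFDB input, and a small CLI.

## Worked example

```r
library(ecgarch)

# 6 labelled one-minute segments with apnea-like volatility, known truth
segs <- simulate_ecg_segments("apnea_like", n_segments = 6, seed = 7)

# 1. is there anything for a variance model to do?
run_battery(segs)[, c("label", "kurtosis", "skewness", "engle_stat", "engle_h")]
#> # A tibble: 6 x 5
#>   label kurtosis skewness engle_stat engle_h
#>   <chr>    <dbl>    <dbl>      <dbl>   <int>
#> 1 apnea     8.02    1.26       2489.       1
#> 2 apnea     7.66    0.955      2469.       1
#> 3 apnea     8.20    0.973      2299.       1
#> 4 apnea     8.43    1.25       2508.       1
#> 5 apnea     8.45    1.32       2541.       1
#> 6 apnea     9.14    1.40       2291.       1
```

Kurtosis far above the Gaussian 3 and an ARCH-LM statistic orders of
magnitude beyond the 3.8415 critical value: the segments are heavy-tailed
and conditionally heteroskedastic, so a GARCH-family model is warranted.

```r
# 2. fit the composite to one segment and inspect it
x <- segs$samples[[1]]
fit <- fit_composite(x, arima_order = c(1, 0, 1), vol = vol_orders("egarch", 1, 1))
tidy(fit)
#> # A tibble: 8 x 4
#>   component term   estimate role
#>   <chr>     <chr>     <dbl> <chr>
#> 1 mean      ar1      0.511  autoregressive
#> 2 mean      ma1      0.340  moving_average
#> 3 mean      mean     0.0334 level
#> 4 variance  alpha0  -0.857  level
#> 5 variance  alpha1   1      shock
#> 6 variance  beta1    0.795  persistence
#> 7 variance  theta    0.0573 sign
#> 8 variance  lambda   0.625  magnitude
```

The mean part lands on the regime's generating ARMA values (0.5, 0.3). The
variance part reports strong volatility persistence (`beta1` 0.80) and a
large shock magnitude (`lambda` 0.63): the fitted EGARCH is absorbing both
the noise clustering and the beat spikes that remain in the mean residuals,
which is exactly its role in the composite. (Clean recovery of volatility
truth — within 0.05 per coefficient — is demonstrated on beat-free composite
simulations by the test suite and the acceptance script.) `alpha1` is the
fixed EGARCH scale normalisation.

```r
# 3. compare model families on all segments, held out 50/50
sp <- split_segments(segs, 0.5, seed = 1)
fits <- model_segments(sp[sp$role == "eval", ], model = "arima-egarch",
                       arima_order = c(1, 0, 1), vol = vol_orders("egarch", 1, 1))
aggregate_metrics(fits)
#> # A tibble: 1 x 11
#>   label model        n_segments mse_mean   mse_sd rmse_mean rmse_sd ...
#> 1 apnea arima-egarch          3   0.0181 0.000975     0.134 0.00361 ...
```

`autoplot(fit)` draws the observed segment against its one-step fitted
values with the conditional `± sigma_t` envelope — the volatility bursts are
visible as a widening band.

A shell entry point wraps the same functions
(`system.file("exec", "ecgarch", package = "ecgarch")`):

```sh
ecgarch simulate --regime apnea_like --n-segments 10 --seed 1 --out fixtures/
ecgarch test-arch --in fixtures/ --out battery
ecgarch fit --in fixtures/ --model arima-egarch --orders 1,0,1 --vol-orders 1,1 --out report
```

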