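---
title: "Modelling ECG segments with ARIMA and GARCH-family volatility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ECG segments with ARIMA and GARCH-family volatility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgarch)
```

## The model

A one-minute single-lead ECG segment (6000 samples at 100 Hz) is treated as a
stochastic process whose mean *and* variance change over time. The package
decomposes this nonstationarity additively:

* a **linear conditional-mean part**, ARIMA(p, d, q): after differencing
  `d` times, `w_t = sum(a_k w_{t-k}) + eps_t + sum(b_k eps_{t-k})`;
* a **nonlinear conditional-variance part** on the innovations,
  `eps_t = sigma_t Z_t` with `Z_t ~ N(0, 1)` and `sigma_t^2` following an
  ARCH, GARCH, GJR-GARCH or EGARCH recursion.

GARCH lets variance persist (`sigma2_t = alpha0 + sum(alpha_i y_{t-i}^2) +
sum(beta_j sigma2_{t-j})`), GJR lets negative shocks raise variance more than
positive ones through an indicator term, and EGARCH models the *logarithm*
of variance through `g(Z) = theta Z + lambda (|Z| - sqrt(2/pi))`, so its
coefficients need no sign restrictions. The composite ARIMA-EGARCH model is
the package's centrepiece: the mean model captures the linear structure, the
EGARCH part the volatility clustering left in the residuals.

Two notational warnings, both documented on `vol_orders()`:

* In the EGARCH equation as printed in the source model, the Greek letters
  attach in the reverse of the usual convention (the `beta`-named
  coefficients multiply the shock terms `g(Z)`, the `alpha`-named ones the
  lagged log-variances). The package names parameters by *role*: `alpha` are
  shock coefficients (q of them), `beta` persistence coefficients (p), for
  every family.
* Selected-model labels like "GARCH(1,4)" or "EGARCH(1,5)" are read as
  p = 1 persistence lag and q = 4 or 5 shock lags, consistent with the
  "GARCH(p, q)" ordering used when the recursions are defined. The tuple
  order is never spelled out alongside those labels, so this is a documented
  convention; both orderings are a one-line change in `vol_orders()`.

## Estimation

Everything is Gaussian **quasi-maximum likelihood**, written from scratch:

* **ARIMA** uses the conditional (CSS) likelihood: the residual recursion
  runs with zero pre-sample values and the Gaussian log-density is summed
  over `t > max(p, q)`; the innovation variance is profiled out. The mean of
  the differenced series is removed before fitting and restored in fitted
  values (the model equations carry no intercept; subtracting the mean keeps
  `d = 2` segments well-behaved). Stationarity and invertibility are
  enforced by a partial-autocorrelation reparameterisation (Levinson
  recursion, `tanh`-mapped), so BFGS plus a Nelder-Mead polish run
  unconstrained from a Hannan-Rissanen starting point (long-AR residual
  regression). At segment length (6000), CSS and exact likelihood coincide
  for practical purposes; `stats::arima(method = "CSS")` serves as an
  independent oracle in the test suite, never as the implementation.
* **Volatility models** initialise pre-sample variances at the sample
  variance of the series (the first `max(p, q)` path values carry that
  initialisation and the likelihood conditions on them) and pre-sample
  shocks at zero. Positivity and stationarity are imposed through log
  transforms plus a persistence barrier; EGARCH persistence through a
  `tanh` map. Because the scale of `g(.)` and the shock coefficients
  multiplying it are only jointly identified, EGARCH estimation fixes the
  first shock coefficient at 1 — `theta` and `lambda` then carry the sign
  and magnitude response, the standard EGARCH(1,1) form.
* **Ridge safeguard.** On (near-)homoskedastic data the likelihood is flat
  along the zero-shock ridge, where persistence is unidentified; an
  optimiser will happily report `alpha ~ 0.003, beta ~ 0.86` with a
  likelihood edge of a fraction of a nat. `fit_volatility()` therefore runs
  two deterministic starts (persistent and conservative) plus a
  constant-variance candidate and resolves likelihood ties — differences
  under 3 nats, well inside likelihood-ratio noise for these parameter
  counts — toward the least persistent representation. Informative data
  override this by hundreds of nats.
* **Composite fitting** is three-stage: ARIMA, then volatility on its
  residuals, then (by default) *joint refinement* of mean and variance
  parameters maximising the heteroskedasticity-weighted likelihood from the
  two-stage solution. Refinement can only improve that objective; on
  divergence the two-stage estimates are kept and flagged. A strictly
  two-stage composite has exactly the ARIMA conditional mean, so joint
  refinement is what lets the composite's mean parameters gain efficiency
  under volatility clustering; both modes are selectable.

## Order selection and evaluation

`information_criterion()` implements the per-observation normalised forms
`AIC = 2k/n - 2 loglik/n`, `BIC = k ln(n)/n - 2 loglik/n`; for fixed `n`
they rank models identically to the classical criteria. `k` counts the
innovation variance for ARIMA and every estimated coefficient including
`alpha0` for volatility models.

`select_orders()` re-evaluates every candidate's likelihood on the **common
conditioning sample** (observations after `max(d + max(p, q))` over the
grid, variance re-profiled). Conditional likelihoods conditioned on each
candidate's own lag count are not comparable: bigger models silently drop
more burn-in-contaminated residuals, and in simulation that alone produced
spurious AR(3) selections over an ARMA(2,1) truth. Ties break toward fewer
parameters, then lexicographically smaller orders.

Per-segment fit quality uses MSE, RMSE (`sqrt(MSE)` exactly), MAE, and MAPE.
ECG amplitudes cross zero, where MAPE's division is undefined: by default
zero-observation indices are excluded and counted, with the naive division
available behind `mape_mode = "naive"` (the huge MAPE standard deviations
sometimes reported suggest the naive form). One-step fitted values copy the
observation over the first `d + max(p, q)` positions (no prediction exists
there), so every metric is defined over the full segment; all model families
share the convention. A pure volatility model has zero conditional mean, so
its "fitted curve" is the segment mean with the `sigma_t` envelope exported
separately — that is the only sense in which a variance-only model traces a
signal.

The evaluation protocol is **held-out**: orders (and, in the model
comparison, coefficients) are estimated on a random half of the segments
(`split_segments()`, round-half-up, seed-deterministic) and one-step errors
are measured on the other half. This matters for interpreting the model
ranking: *in sample* the CSS ARIMA estimate is the exact least-squares
minimiser of the evaluated one-step MSE, so no re-weighted estimator can
beat it there; out of sample the heteroskedasticity-weighted composite is
the more efficient estimator and its MSE advantage is real, if small. The
package's acceptance experiment (50 simulated composite segments, 25
estimation / 25 evaluation pairs) measures exactly that ordering.

## The synthetic generator

`simulate_ecg_segments()` produces labelled segments carrying the
statistical structure the diagnostics target, with all truth recorded:

* a quasi-periodic train of Gaussian-bump "beats" (0.9 mV, ~1.1 Hz with
  jittered intervals, 12 ms width) — the nonstationary mean;
* plus stationary ARMA(1,1) noise (`ar = 0.5, ma = 0.3`) driven by EGARCH
  innovations with unconditional variance 0.01 (0.1 mV noise under 0.9 mV
  beats). The **apnea-like** regime uses persistence 0.95, magnitude 0.35,
  sign -0.10; the **normal-like** regime 0.80 / 0.15 / -0.05; the
  **homoskedastic control** zeroes all dynamics *and* the beat train, so its
  segments are i.i.d. Gaussian — the exact null of the heteroskedasticity
  tests. Values live in `inst/extdata/regimes.conf`, not in code.

An earlier design carried the noise through a first difference; the
random-walk level wander then dominated the beats and made segments
platykurtic, so the regimes use stationary noise and leave the mean
nonstationarity to the beats. Two consequences worth knowing: on raw
beat-carrying segments the ARCH-LM statistic is dominated by the beat train
(every segment rejects, as every real ECG segment does), so the two regimes
separate through the ARCH-LM statistic of their *noise processes* and
through the fitted EGARCH parameters, not through the raw-segment statistic;
and the surrogate makes no claim of morphological fidelity — it exists so
that heavy tails (kurtosis > 3), volatility clustering and a beat-like mean
are all present with known truth. Passing tests on it demonstrate correct
recovery of known structure, not performance on physiological recordings.

## Diagnostics

* `moment_summary()` uses population (biased) moment estimators, matching
  the expectation-form definitions; kurtosis 3 is the Gaussian reference,
  and kurtosis is bounded below by 1 with equality at a symmetric two-point
  sample.
* `engle_arch_test()` regresses squared demeaned residuals on a constant and
  `lags` lags; `n * R^2` is chi-square with `lags` df under the null. The
  default one lag reproduces the 3.8415 critical value at 5%; the statistic
  is scale-free.
* `wilcoxon_signed_rank()` implements the tie-adjusted normal approximation
  exactly as printed: `tieadj = sum(t^3 - t)/2` over tied groups makes the
  denominator the classical tie-corrected variance; zero differences are
  dropped, midranks used, and no continuity correction applied. Against the
  exhaustive enumeration null the z-score's centring and variance agree
  exactly, and the normal p tracks the exact two-sided mid-p within 0.01
  across the rejection-relevant band (exact p <= 0.2) for n >= 8; for
  smaller n the lattice is too coarse for any normal approximation.
* `distribution_compare()` reports shared-bin histograms, a Gaussian
  reference at the first sample's moments, both ECDFs and the KS distance —
  the numeric stand-in for the visual histogram/CDF check. The paired
  comparison in `run_battery()` pairs a segment, by sample index, with an
  equal-length series simulated from a fitted GARCH-family model; the
  pairing is this package's documented interpretation of "model versus
  segment" testing.

## Numerical choices and problem sizes

Tolerance 1e-8 (relative) on all objectives; optimisers are deterministic,
so identical input and options give bit-identical coefficients. Defaults
shipped for ECG work are ARIMA(5, 2, 4) with EGARCH(1, 5) — the orders most
often selected by BIC on the apnea study data — and one Engle lag; all are
configuration, not constants. The test-suite and acceptance problem sizes
are chosen to make the statistical claims sharp at desk scale: recovery runs
20 seeds at n = 20000 per family (simulation-average coefficient error under
0.05), calibration 10000 replicates (size 5% within one point), selection
consistency 20 seeds at n = 6000 over a 32-candidate grid with an ARMA(2,1)
truth at `ar = (1.2, -0.8), ma = 0.5` (complex AR roots — a truth near
pole-zero cancellation, e.g. `ar = (0.5, 0.25)`, is legitimately reported at
lower order by BIC), and the model-ordering experiment 50 segments of 6000
samples.

## Limitations

* Gaussian innovations only; heavy-tailed innovation families (Student-t,
  GED) are out of scope, as are integrated and multivariate GARCH and
  multi-step forecasting.
* The CSS likelihood conditions on pre-sample zeros; for very short series
  or near-unit-root MA parts an exact state-space likelihood would differ.
* No apnea *classification* is provided anywhere in the package — the
  models describe segments; using fitted parameters as classifier features
  is downstream work.
* WFDB reading covers the formats the apnea database uses (16, 212, per-
  minute annotations); it is a convenience, and the CSV dialect is the
  supported interchange format.
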