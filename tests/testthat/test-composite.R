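test_that("joint refinement recovers composite generating parameters", {
  sim <- simulate_composite(list(ar = 0.6, ma = 0.3, d = 0), egarch_truth(),
                            n = 20000, seed = 81)
  fit <- fit_composite(sim$x, c(1, 0, 1), vol_orders("egarch", 1, 1))
  expect_lt(abs(fit$ar - 0.6), 0.05)
  expect_lt(abs(fit$ma - 0.3), 0.05)
  expect_lt(abs(fit$vol_params$beta - 0.9), 0.05)
  expect_lt(abs(fit$vol_params$lambda - 0.2), 0.05)
  expect_lt(fit$vol_params$theta, 0)
  expect_gte(fit$joint_loglik, fit$two_stage_loglik)
})

test_that("joint refinement cannot worsen the objective and beats a
           constant-variance likelihood under heteroskedasticity", {
  sim <- simulate_composite(list(ar = 0.5, ma = 0, d = 0), egarch_truth(),
                            n = 6000, seed = 82)
  fit <- fit_composite(sim$x, c(1, 0, 0), vol_orders("egarch", 1, 1))
  expect_gte(fit$joint_loglik, fit$two_stage_loglik)
  # pure-Gaussian (constant variance) likelihood of the stage-1 fit on the
  # same conditioning set
  eps <- fit$arima$residuals
  idx <- (fit$t0 + 1):length(eps)
  s2 <- mean(eps[idx]^2)
  ll_const <- -0.5 * length(idx) * (log(2 * pi * s2) + 1)
  expect_gt(fit$joint_loglik, ll_const)
})

test_that("homoskedastic input leaves the stage-1 mean coefficients in place", {
  x <- sim_arma(8000, ar = 0.5, ma = 0.2, seed = 83)
  fit <- fit_composite(x, c(1, 0, 1), vol_orders("egarch", 1, 1))
  expect_lt(abs(fit$ar - fit$arima$ar), 0.02)
  expect_lt(abs(fit$ma - fit$arima$ma), 0.02)
})

test_that("two-stage mode reproduces the plain ARIMA fitted values exactly", {
  sim <- simulate_composite(list(ar = 0.5, ma = 0.3, d = 1), egarch_truth(),
                            n = 4000, seed = 84)
  fit <- fit_composite(sim$x, c(1, 1, 1), vol_orders("egarch", 1, 1),
                       mode = "two-stage")
  expect_identical(fitted_values(fit), fitted_values(fit$arima))
})

test_that("composite fitted values share the mean-model conventions", {
  # variance-only composite (p = q = 0, d = 0): zero conditional mean
  sim <- simulate_composite(list(d = 0), egarch_truth(), n = 3000, seed = 85)
  x <- sim$x - mean(sim$x)
  fit <- fit_composite(x, c(0, 0, 0), vol_orders("egarch", 1, 1))
  expect_equal(fitted_values(fit), rep(0, 3000), tolerance = 1e-10)
  # d = 1, p = q = 0: the random-walk forecast
  y <- cumsum(withr::with_seed(86, rnorm(3000, sd = 0.5)))
  fd <- fit_composite(y, c(0, 1, 0), vol_orders("egarch", 1, 1))
  fv <- fitted_values(fd)
  expect_equal(fv[-1], y[-length(y)] + mean(diff(y)), tolerance = 1e-12)
  # new-data prediction keeps the same algebra
  y2 <- cumsum(withr::with_seed(87, rnorm(500, sd = 0.5)))
  expect_equal(fitted_values(fd, y2)[-1], y2[-length(y2)] + fd$mean, tolerance = 1e-12)
})

test_that("a pure volatility model predicts zero with the sample-variance MSE", {
  sim <- simulate_volatility(vol_orders("egarch", 1, 1), egarch_truth(),
                             n = 6000, seed = 88)
  fit <- fit_volatility(sim$y, vol_orders("egarch", 1, 1))
  fv <- fitted_values(fit)
  m <- max(fit$orders$p, fit$orders$q)
  expect_true(all(fv[-seq_len(m)] == 0))
  met <- error_metrics(sim$y, fv)
  expect_equal(met$mse, mean(sim$y[-seq_len(m)]^2) * (6000 - m) / 6000,
               tolerance = 1e-10)
  # +/- sigma_t envelope covers about the Gaussian 68%
  cover <- mean(abs(sim$y) < sqrt(fit$sigma2_path))
  expect_gt(cover, 0.62)
  expect_lt(cover, 0.74)
})

test_that("composite beats stage-1 ARIMA out of sample on average", {
  vp <- vol_params(-0.46051702, alpha = 1, beta = 0.95, theta = -0.1, lambda = 0.35)
  mp <- list(ar = 0.5, ma = 0.3, d = 1)
  res <- vapply(1:6, function(i) {
    tr <- simulate_composite(mp, vp, n = 6000, seed = 500 + i)$x
    ev <- simulate_composite(mp, vp, n = 6000, seed = 900 + i)$x
    fa <- fit_arima(tr, c(1, 1, 1))
    fc <- fit_composite(tr, c(1, 1, 1), vol_orders("egarch", 1, 1))
    c(error_metrics(ev, fitted_values(fa, ev))$mse,
      error_metrics(ev, fitted_values(fc, ev))$mse)
  }, c(0, 0))
  expect_lt(mean(res[2, ]), mean(res[1, ]))
})

test_that("composite reports serialise through tidy, glance and fit_report", {
  sim <- simulate_composite(list(ar = 0.5, ma = 0, d = 0), egarch_truth(),
                            n = 3000, seed = 89)
  fit <- fit_composite(sim$x, c(1, 0, 0), vol_orders("egarch", 1, 1))
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("mean", "variance"))
  expect_equal(td$estimate[td$term == "ar1"], fit$ar)
  gl <- glance(fit)
  expect_equal(gl$joint_loglik, fit$joint_loglik)
  rep <- fit_report(fit)
  back <- jsonlite::parse_json(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA))
  expect_equal(back$joint_loglik, fit$joint_loglik)
  expect_s3_class(autoplot(fit), "ggplot")
})
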