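test_that("difference and undifference are exact inverses for d in 0..2", {
  expect_equal(difference(c(1, 4, 9, 16), 1), c(3, 5, 7))
  expect_equal(difference(c(1, 4, 9, 16), 2), c(2, 2))
  x0 <- rnorm(20)
  expect_identical(difference(x0, 0), x0)
  expect_identical(undifference(x0, 0), x0)
  expect_equal(undifference(c(3, 5, 7), 1, 1), c(1, 4, 9, 16))
  expect_equal(undifference(c(2, 2), 2, c(1, 4)), c(1, 4, 9, 16))
  for (d in 0:2) {
    for (s in 1:5) {
      x <- withr::with_seed(s, rnorm(50 + s))
      expect_equal(undifference(difference(x, d), d, x[seq_len(d)]), x)
    }
  }
  expect_error(difference(rnorm(10), 3), "0, 1 or 2")
  expect_error(undifference(rnorm(10), 2, 1), "length d")
})

test_that("conditional ARMA likelihood matches hand-derived values", {
  # pure noise on zeros: sum of standard-normal log densities
  r <- arima_loglik(c(0, 0, 0), sigma2 = 1)
  expect_equal(r$loglik, -1.5 * log(2 * pi))
  # zero AR coefficient reduces to the same value (one obs conditioned away)
  r1 <- arima_loglik(c(0, 0, 0), ar = 0, sigma2 = 1)
  expect_equal(r1$loglik, -1 * log(2 * pi))
  # AR(1) hand recursion on x = (1, 1): eps_2 = 1 - 0.5 * 1
  r2 <- arima_loglik(c(1, 1), ar = 0.5, sigma2 = 1)
  expect_equal(r2$residuals, c(1, 0.5))
  expect_equal(r2$loglik, -0.5 * (log(2 * pi) + 0.25))
  # explosive MA recursion flags -Inf, no error
  r3 <- arima_loglik(rnorm(500), ma = 3, sigma2 = 1)
  expect_identical(r3$loglik, -Inf)
})

test_that("quasi-MLE recovers ARMA(1,1) and agrees with the CSS oracle", {
  x <- sim_arma(20000, ar = 0.6, ma = 0.3, seed = 11)
  fit <- fit_arima(x, c(1, 0, 1))
  expect_lt(abs(fit$ar - 0.6), 0.05)
  expect_lt(abs(fit$ma - 0.3), 0.05)
  expect_lt(abs(fit$sigma2 - 1), 0.05)
  oracle <- stats::arima(x, c(1, 0, 1), method = "CSS", include.mean = FALSE)
  expect_lt(abs(fit$ar - unname(coef(oracle)["ar1"])), 0.005)
  expect_lt(abs(fit$ma - unname(coef(oracle)["ma1"])), 0.005)
  # loglik at the optimum is at least the loglik at the truth
  wc <- x - mean(x)
  ll_truth <- arima_loglik(wc, ar = 0.6, ma = 0.3, sigma2 = 1)$loglik
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("white-noise fit gives the sample mean square as variance", {
  x <- withr::with_seed(2, rnorm(5000, sd = 2))
  fit <- fit_arima(x, c(0, 0, 0))
  expect_equal(fit$sigma2, mean((x - mean(x))^2), tolerance = 1e-12)
})

test_that("integrated series are recovered with d = 1 and punished with d = 0", {
  dx <- sim_arma(6000, ar = 0.5, seed = 21)
  x <- undifference(dx, 1, 0)
  f1 <- fit_arima(x, c(1, 1, 0))
  expect_lt(abs(f1$ar - 0.5), 0.05)
  f0 <- fit_arima(x, c(1, 0, 0))
  b1 <- information_criterion("bic", f1$n_params, f1$n_eff, f1$loglik)$value
  b0 <- information_criterion("bic", f0$n_params, f0$n_eff, f0$loglik)$value
  expect_lt(b1, b0)
})

test_that("estimator bias shrinks as the sample grows", {
  mae_at <- function(n) {
    mean(vapply(1:8, function(s) {
      x <- sim_arma(n, ar = 0.6, ma = 0.3, seed = 100 * s)
      abs(fit_arima(x, c(1, 0, 1))$ar - 0.6)
    }, 0))
  }
  m <- c(mae_at(500), mae_at(2000), mae_at(20000))
  expect_lt(m[2], m[1] + 0.01) # monotone within Monte-Carlo slack
  expect_lt(m[3], m[2] + 0.005)
  expect_lt(m[3], m[1])
})

test_that("fits are bit-identical across repeated runs", {
  x <- sim_arma(3000, ar = 0.4, ma = 0.2, seed = 5)
  f1 <- fit_arima(x, c(1, 0, 1))
  f2 <- fit_arima(x, c(1, 0, 1))
  expect_identical(c(f1$ar, f1$ma, f1$sigma2), c(f2$ar, f2$ma, f2$sigma2))
})

test_that("one-step fitted values follow the integration algebra", {
  # d = 0, p = q = 0: prediction is the (zero) mean at every predicted index
  x <- withr::with_seed(3, rnorm(500))
  x <- x - mean(x)
  f <- fit_arima(x, c(0, 0, 0))
  expect_equal(fitted_values(f), rep(0, 500), tolerance = 1e-12)

  # d = 1, p = q = 0: random-walk one-step forecast x_{t-1} plus drift
  y <- cumsum(withr::with_seed(4, rnorm(800)))
  fd <- fit_arima(y, c(0, 1, 0))
  fv <- fitted_values(fd)
  drift <- mean(diff(y))
  expect_equal(fv[1], y[1]) # no-prediction position copies the observation
  expect_equal(fv[-1], y[-length(y)] + drift, tolerance = 1e-12)

  # observed - fitted equals the model innovations at predicted indices
  x2 <- sim_arma(1000, ar = 0.5, ma = 0.2, seed = 6)
  f2 <- fit_arima(x2, c(1, 0, 1))
  fv2 <- fitted_values(f2)
  expect_equal((x2 - fv2)[-1], f2$residuals[-1], tolerance = 1e-12)
  expect_equal(fv2[1], x2[1])
  expect_error(fitted_values(f2, rnorm(1)), "too short")
})

test_that("tidy and glance report the fitted parameters", {
  x <- sim_arma(2000, ar = 0.5, seed = 7)
  f <- fit_arima(x, c(1, 0, 0))
  td <- tidy(f)
  expect_setequal(td$term, c("ar1", "mean", "sigma2"))
  expect_equal(td$estimate[td$term == "ar1"], f$ar)
  gl <- glance(f)
  expect_equal(gl$loglik, f$loglik)
  expect_equal(gl$bic, information_criterion("bic", 2, f$n_eff, f$loglik)$value)
  expect_s3_class(autoplot(f), "ggplot")
})
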