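#' Difference and integrate a series
#'
#' `difference()` applies the lag-1 differencing operator `(1 - L)` `d` times
#' (`L x_t = x_{t-1}`); `undifference()` is its exact inverse given the first
#' `d` values of the original series. Differencing up to order 2 is how the
#' mean model removes slow nonstationary trends from an ECG amplitude series
#' before ARMA fitting.
#'
#' @param x,dx Numeric vector (original / differenced series).
#' @param d Differencing order, one of 0, 1, 2.
#' @param initial_values Numeric vector of length `d`: the first `d` values of
#'   the series being reconstructed.
#' @return A numeric vector of length `length(x) - d` (for `difference()`) or
#'   `length(dx) + d` (for `undifference()`).
#' @examples
#' difference(c(1, 4, 9, 16), 1)        # 3 5 7
#' undifference(c(3, 5, 7), 1, 1)       # 1 4 9 16
#' @export
difference <- function(x, d) {
  d <- assert_count(d, "d")
  if (d > 2) abort("`d` must be 0, 1 or 2.")
  x <- assert_numeric_vector(x, "x")
  if (length(x) <= d) abort("`x` must be longer than `d`.")
  if (d == 0) x else diff(x, differences = d)
}

#' @rdname difference
#' @export
undifference <- function(dx, d, initial_values = numeric(0)) {
  d <- assert_count(d, "d")
  if (d > 2) abort("`d` must be 0, 1 or 2.")
  if (length(initial_values) != d) {
    abort(sprintf("`initial_values` must have length d = %d.", d))
  }
  if (d == 0) return(as.numeric(dx))
  as.numeric(diffinv(dx, differences = d, xi = as.numeric(initial_values)))
}

# Partial-autocorrelation (Barndorff-Nielsen/Schou) parameterisation ----------
# Maps a vector of partial autocorrelations in (-1,1)^p to the coefficients of
# a stationary AR polynomial 1 - sum a_k L^k, and back. Optimisers work on
# atanh(pacf), which is unconstrained.

pacf_to_ar <- function(pac) {
  a <- numeric(0)
  for (k in seq_along(pac)) {
    a <- if (k == 1) pac[1] else c(a - pac[k] * rev(a), pac[k])
  }
  a
}

ar_to_pacf <- function(a) {
  p <- length(a)
  pac <- numeric(p)
  while (p > 0) {
    pac[p] <- a[p]
    if (p > 1) {
      if (abs(1 - a[p]^2) < 1e-12) return(rep(NA_real_, length(pac)))
      a <- (a[-p] + a[p] * rev(a[-p])) / (1 - a[p]^2)
    }
    p <- p - 1
  }
  pac
}

# Safe inverse transform: falls back to zeros when the initial guess is outside
# the stationary/invertible region.
coef_to_unconstrained <- function(coefs, negate = FALSE) {
  if (length(coefs) == 0) return(numeric(0))
  pac <- ar_to_pacf(if (negate) -coefs else coefs)
  if (anyNA(pac) || any(abs(pac) >= 0.999)) return(rep(0, length(coefs)))
  atanh(pac)
}

#' Conditional Gaussian log-likelihood of an ARMA model
#'
#' Evaluates the conditional-sum-of-squares (CSS) quasi-likelihood of an
#' ARMA(p, q) model with given coefficients on an already-differenced series.
#' Residuals follow the recursion
#' `eps_t = w_t - sum(ar_k w_{t-k}) - sum(ma_k eps_{t-k})` with all pre-sample
#' values set to zero, and the Gaussian log-density is summed over
#' `t = max(p, q) + 1, ..., n`. An explosive MA recursion yields
#' `loglik = -Inf` rather than an error, so optimisers can treat it as an
#' invalid point.
#'
#' @param x Numeric series, already differenced (and demeaned if desired).
#' @param ar,ma Coefficient vectors (may be empty).
#' @param sigma2 Innovation variance (> 0).
#' @return A list with `loglik` (nats), `residuals` (same length as `x`) and
#'   `n_eff`, the number of conditioning observations.
#' @export
arima_loglik <- function(x, ar = numeric(0), ma = numeric(0), sigma2 = 1) {
  x <- assert_numeric_vector(x, "x")
  sigma2 <- assert_scalar_number(sigma2, "sigma2")
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  eps <- arma_residuals_cpp(x, as.numeric(ar), as.numeric(ma))
  m <- max(length(ar), length(ma))
  n <- length(x)
  if (n <= m) abort("Series shorter than the conditioning window.")
  e <- eps[(m + 1):n]
  if (any(!is.finite(e))) {
    return(list(loglik = -Inf, residuals = eps, n_eff = n - m))
  }
  ll <- sum(-0.5 * (log(2 * pi * sigma2) + e^2 / sigma2))
  list(loglik = ll, residuals = eps, n_eff = n - m)
}

# Concentrated negative loglik in transformed parameter space.
arma_css_obj <- function(par, wc, p, q, m, n_eff) {
  ar <- if (p > 0) pacf_to_ar(tanh(par[seq_len(p)])) else numeric(0)
  ma <- if (q > 0) -pacf_to_ar(tanh(par[p + seq_len(q)])) else numeric(0)
  eps <- arma_residuals_cpp(wc, ar, ma)
  e <- eps[(m + 1):length(wc)]
  s2 <- mean(e * e)
  if (!is.finite(s2) || s2 <= 0) return(1e10)
  0.5 * n_eff * (log(2 * pi * s2) + 1)
}

# Hannan-Rissanen-style initial guess: long-AR residuals, then OLS of the
# series on its own lags and the residual lags.
hannan_rissanen <- function(wc, p, q) {
  n <- length(wc)
  if (p + q == 0) return(list(ar = numeric(0), ma = numeric(0)))
  if (q == 0) {
    X <- stats::embed(wc, p + 1)
    cf <- tryCatch(stats::lm.fit(X[, -1, drop = FALSE], X[, 1])$coefficients,
                   error = function(e) rep(0, p))
    return(list(ar = ifelse(is.finite(cf), cf, 0), ma = numeric(0)))
  }
  m_long <- min(max(20L, p + q + 5L), max(2L, n %/% 4L))
  e <- tryCatch({
    fit <- stats::ar(wc, aic = FALSE, order.max = m_long, method = "yule-walker",
                     demean = FALSE)
    r <- as.numeric(fit$resid)
    r[!is.finite(r)] <- 0
    r
  }, error = function(e) rep(0, n))
  m <- max(p, q)
  idx <- (m + 1):n
  X <- cbind(
    if (p > 0) sapply(seq_len(p), function(k) wc[idx - k]) else NULL,
    sapply(seq_len(q), function(k) e[idx - k])
  )
  cf <- tryCatch(stats::lm.fit(X, wc[idx])$coefficients, error = function(e) rep(0, p + q))
  cf[!is.finite(cf)] <- 0
  list(ar = cf[seq_len(p)], ma = if (q > 0) cf[p + seq_len(q)] else numeric(0))
}

#' Fit an ARIMA(p, d, q) model by conditional Gaussian quasi-maximum likelihood
#'
#' The series is differenced `d` times, its mean removed, and the ARMA
#' coefficients estimated by maximising the conditional (CSS) Gaussian
#' likelihood of [arima_loglik()], with the innovation variance profiled out.
#' Stationarity of the AR polynomial and invertibility of the MA polynomial
#' are enforced through a partial-autocorrelation reparameterisation, so the
#' optimiser (BFGS with a Nelder-Mead fallback, started from a
#' Hannan-Rissanen regression) works in an unconstrained space. The fit is
#' fully deterministic.
#'
#' @param x Numeric amplitude series (length at least `10 * (p + q + 1) + d`).
#' @param order Integer vector `c(p, d, q)` with `d` in 0..2.
#' @param include_mean Subtract the mean of the differenced series before
#'   fitting and add it back in fitted values (default TRUE).
#' @param max_iter Maximum optimiser iterations (default 500).
#' @param tol Relative convergence tolerance on the objective (default 1e-8).
#' @return An object of class `ecg_arima`: orders, `ar`, `ma`, `mean`,
#'   `sigma2`, `residuals` (innovations of the differenced series), `loglik`,
#'   `n_params`, `converged`, and the input series `x`.
#' @seealso [fitted_values()], [tidy.ecg_arima()], [fit_volatility()],
#'   [fit_composite()]
#' @examples
#' x <- as.numeric(arima.sim(list(ar = 0.6, ma = 0.3), n = 2000))
#' fit <- fit_arima(x, order = c(1, 0, 1))
#' tidy(fit)
#' @export
fit_arima <- function(x, order = c(1, 0, 0), include_mean = TRUE,
                      max_iter = 500, tol = 1e-8) {
  x <- assert_numeric_vector(x, "x")
  if (length(order) != 3) abort("`order` must be c(p, d, q).")
  p <- assert_count(order[1], "p"); d <- assert_count(order[2], "d")
  q <- assert_count(order[3], "q")
  if (d > 2) abort("`d` must be 0, 1 or 2.")
  if (length(x) < 10 * (p + q + 1) + d) {
    abort(sprintf("Series too short: need at least %d observations for ARIMA(%d,%d,%d).",
                  10 * (p + q + 1) + d, p, d, q))
  }
  w <- difference(x, d)
  mu <- if (include_mean) mean(w) else 0
  wc <- w - mu
  m <- max(p, q)
  nd <- length(wc)
  n_eff <- nd - m

  converged <- TRUE
  if (p + q == 0) {
    ar <- numeric(0); ma <- numeric(0)
  } else {
    init <- hannan_rissanen(wc, p, q)
    par0 <- c(coef_to_unconstrained(init$ar), coef_to_unconstrained(init$ma, negate = TRUE))
    fn <- function(par) arma_css_obj(par, wc, p, q, m, n_eff)
    opt <- optim(par0, fn, method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol))
    best <- if (length(par0) > 1) {
      opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
                    control = list(maxit = 10 * max_iter, reltol = tol))
      if (opt2$value < opt$value) opt2 else opt
    } else {
      opt
    }
    converged <- best$convergence == 0
    par <- best$par
    ar <- if (p > 0) pacf_to_ar(tanh(par[seq_len(p)])) else numeric(0)
    ma <- if (q > 0) -pacf_to_ar(tanh(par[p + seq_len(q)])) else numeric(0)
  }
  eps <- arma_residuals_cpp(wc, ar, ma)
  e <- eps[(m + 1):nd]
  sigma2 <- mean(e * e)
  loglik <- sum(-0.5 * (log(2 * pi * sigma2) + e^2 / sigma2))
  structure(list(
    orders = list(p = p, d = d, q = q),
    ar = as.numeric(ar), ma = as.numeric(ma),
    mean = mu, sigma2 = sigma2,
    residuals = as.numeric(eps),
    loglik = loglik, n_eff = n_eff, n_obs = nd,
    n_params = p + q + 1L,
    converged = converged,
    x = x
  ), class = "ecg_arima")
}

#' One-step-ahead fitted values on the original amplitude scale
#'
#' Returns the conditional mean of each observation given its past, mapped
#' back through the integration relation, so `observed - fitted` equals the
#' model innovation. The first `d + max(p, q)` positions carry no prediction
#' and copy the observation (zero error there), keeping every segment metric
#' defined over the full segment length; this convention is shared by all
#' model families in the package.
#'
#' @param fit A fitted `ecg_arima`, `ecg_volatility` or `ecg_composite` object.
#' @param x Optional new series to predict (same convention); defaults to the
#'   series the model was fitted to.
#' @return Numeric vector, `length(x)`.
#' @export
fitted_values <- function(fit, x = NULL) UseMethod("fitted_values")

#' @rdname fitted_values
#' @export
fitted_values.ecg_arima <- function(fit, x = NULL) {
  if (is.null(x)) x <- fit$x
  x <- assert_numeric_vector(x, "x")
  arma_one_step_fitted(x, fit$orders$d, fit$ar, fit$ma, fit$mean)
}

arma_one_step_fitted <- function(x, d, ar, ma, mu) {
  if (length(x) <= d + max(length(ar), length(ma))) {
    abort("Series too short for one-step fitted values with these orders.")
  }
  wc <- difference(x, d) - mu
  eps <- arma_residuals_cpp(wc, ar, ma)
  m <- max(length(ar), length(ma))
  fitted <- x
  idx <- (d + m + 1):length(x)
  fitted[idx] <- x[idx] - eps[idx - d]
  fitted
}

#' @export
print.ecg_arima <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d) conditional-QML fit\n", x$orders$p, x$orders$d, x$orders$q))
  if (length(x$ar)) cat("  ar:   ", paste(sprintf("% .4f", x$ar), collapse = " "), "\n")
  if (length(x$ma)) cat("  ma:   ", paste(sprintf("% .4f", x$ma), collapse = " "), "\n")
  cat(sprintf("  mean: % .6g  sigma2: %.6g\n", x$mean, x$sigma2))
  cat(sprintf("  loglik: %.4f over %d obs%s\n", x$loglik, x$n_eff,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
logLik.ecg_arima <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_eff, class = "logLik")
}

#' @export
residuals.ecg_arima <- function(object, ...) object$residuals
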