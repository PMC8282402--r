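#' Tidy a fitted ARIMA model
#'
#' @param x An `ecg_arima` fit.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, `role`.
#' @export
tidy.ecg_arima <- function(x, ...) {
  tibble(
    term = c(if (length(x$ar)) paste0("ar", seq_along(x$ar)),
             if (length(x$ma)) paste0("ma", seq_along(x$ma)),
             "mean", "sigma2"),
    estimate = c(x$ar, x$ma, x$mean, x$sigma2),
    role = c(rep("autoregressive", length(x$ar)),
             rep("moving_average", length(x$ma)),
             "level", "innovation_variance")
  )
}

#' @rdname tidy.ecg_arima
#' @export
glance.ecg_arima <- function(x, ...) {
  tibble(
    p = x$orders$p, d = x$orders$d, q = x$orders$q,
    sigma2 = x$sigma2, loglik = x$loglik,
    n_params = x$n_params, n_eff = x$n_eff,
    aic = information_criterion("aic", x$n_params, x$n_eff, x$loglik)$value,
    bic = information_criterion("bic", x$n_params, x$n_eff, x$loglik)$value,
    converged = x$converged
  )
}

#' Tidy a fitted volatility model
#'
#' @param x An `ecg_volatility` fit.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `role` (shock / persistence /
#'   asymmetry / sign / magnitude / level).
#' @export
tidy.ecg_volatility <- function(x, ...) {
  p <- x$params; o <- x$orders
  tibble(
    term = c("alpha0", paste0("alpha", seq_len(o$q)),
             if (o$p > 0) paste0("beta", seq_len(o$p)),
             if (o$family == "gjr") paste0("gamma", seq_len(o$q)),
             if (o$family == "egarch") c("theta", "lambda")),
    estimate = c(p$alpha0, p$alpha, p$beta,
                 if (o$family == "gjr") p$gamma,
                 if (o$family == "egarch") c(p$theta, p$lambda)),
    role = c("level", rep("shock", o$q), rep("persistence", o$p),
             if (o$family == "gjr") rep("asymmetry", o$q),
             if (o$family == "egarch") c("sign", "magnitude"))
  )
}

#' @rdname tidy.ecg_volatility
#' @export
glance.ecg_volatility <- function(x, ...) {
  m <- max(x$orders$p, x$orders$q)
  n_eff <- length(x$y) - m
  tibble(
    family = x$orders$family, p = x$orders$p, q = x$orders$q,
    persistence = vol_persistence(x$orders, x$params),
    loglik = x$loglik, n_params = x$n_params, n_eff = n_eff,
    aic = information_criterion("aic", x$n_params, n_eff, x$loglik)$value,
    bic = information_criterion("bic", x$n_params, n_eff, x$loglik)$value,
    converged = x$converged
  )
}

#' Tidy a fitted composite model
#'
#' @param x An `ecg_composite` fit.
#' @param ... Unused.
#' @return A tibble: `component` (`"mean"` / `"variance"`), `term`,
#'   `estimate`, `role`.
#' @export
tidy.ecg_composite <- function(x, ...) {
  mean_tb <- tibble(
    term = c(if (length(x$ar)) paste0("ar", seq_along(x$ar)),
             if (length(x$ma)) paste0("ma", seq_along(x$ma)), "mean"),
    estimate = c(x$ar, x$ma, x$mean),
    role = c(rep("autoregressive", length(x$ar)),
             rep("moving_average", length(x$ma)), "level")
  )
  vol_fake <- structure(list(params = x$vol_params, orders = x$vol_orders),
                        class = "ecg_volatility")
  vol_tb <- tidy.ecg_volatility(vol_fake)
  dplyr::bind_rows(
    dplyr::mutate(mean_tb, component = "mean", .before = 1),
    dplyr::mutate(vol_tb, component = "variance", .before = 1)
  )
}

#' @rdname tidy.ecg_composite
#' @export
glance.ecg_composite <- function(x, ...) {
  n_eff <- length(x$residuals) - x$t0
  tibble(
    mean_order = sprintf("(%d,%d,%d)", x$arima$orders$p, x$arima$orders$d,
                         x$arima$orders$q),
    vol_family = x$vol_orders$family,
    vol_order = sprintf("(%d,%d)", x$vol_orders$p, x$vol_orders$q),
    mode = x$mode,
    joint_loglik = x$joint_loglik, two_stage_loglik = x$two_stage_loglik,
    n_params = x$n_params, n_eff = n_eff,
    bic = information_criterion("bic", x$n_params, n_eff, x$joint_loglik)$value,
    converged = x$converged
  )
}

# JSON-ready fit report shared by all model classes and the CLI `fit`
# subcommand.

#' Serialise a fit as a plain-list report
#'
#' A JSON-ready summary (orders, coefficients, variance, log-likelihood,
#' convergence status) shared by all model classes; the CLI `fit` subcommand
#' writes exactly this structure.
#'
#' @param fit An `ecg_arima`, `ecg_volatility` or `ecg_composite` object.
#' @return A named list safe to pass to [jsonlite::write_json()].
#' @export
fit_report <- function(fit) {
  if (inherits(fit, "ecg_arima")) {
    list(model = "arima",
         orders = fit$orders, ar = fit$ar, ma = fit$ma, mean = fit$mean,
         innovation_variance = fit$sigma2, loglik = fit$loglik,
         n_params = fit$n_params, converged = fit$converged)
  } else if (inherits(fit, "ecg_volatility")) {
    list(model = fit$orders$family,
         orders = list(p = fit$orders$p, q = fit$orders$q),
         params = Filter(Negate(is.null), unclass(fit$params)),
         loglik = fit$loglik, n_params = fit$n_params, converged = fit$converged)
  } else if (inherits(fit, "ecg_composite")) {
    list(model = paste0("arima-", fit$vol_orders$family),
         mean = list(orders = fit$arima$orders, ar = fit$ar, ma = fit$ma,
                     mean = fit$mean),
         variance = list(orders = list(p = fit$vol_orders$p, q = fit$vol_orders$q),
                         family = fit$vol_orders$family,
                         params = Filter(Negate(is.null), unclass(fit$vol_params))),
         mode = fit$mode, joint_loglik = fit$joint_loglik,
         two_stage_loglik = fit$two_stage_loglik,
         n_params = fit$n_params, converged = fit$converged)
  } else {
    abort("`fit` must be an ecgarch model object.")
  }
}
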