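#' Per-observation normalised information criteria
#'
#' The criteria in their per-observation normalised form:
#' `AIC = 2k/n - 2*loglik/n` and `BIC = k*ln(n)/n - 2*loglik/n`. For a fixed
#' `n` these rank models identically to the classical (unnormalised)
#' criteria; the normalised values are what the segment-level model reports
#' print.
#'
#' @param criterion `"aic"` or `"bic"`.
#' @param k Number of estimated parameters (>= 1). The innovation variance
#'   counts as one parameter for ARIMA; every estimated coefficient including
#'   `alpha0` counts for volatility models.
#' @param n Number of observations entering the likelihood (>= 2).
#' @param loglik Log-likelihood in nats.
#' @return A one-row tibble: `criterion`, `k`, `n`, `loglik`, `value`.
#' @examples
#' information_criterion("aic", k = 2, n = 100, loglik = 0)$value # 0.04
#' @export
information_criterion <- function(criterion = c("bic", "aic"), k, n, loglik) {
  criterion <- match.arg(criterion)
  k <- assert_count(k, "k", lower = 1L)
  n <- assert_count(n, "n", lower = 2L)
  loglik <- assert_scalar_number(loglik, "loglik")
  value <- switch(criterion,
    aic = 2 * k / n - 2 * loglik / n,
    bic = k * log(n) / n - 2 * loglik / n
  )
  tibble(criterion = criterion, k = k, n = n, loglik = loglik, value = value)
}

#' Select model orders over a candidate grid
#'
#' Fits every candidate order combination and returns the one minimising the
#' normalised information criterion. Ties are broken by the smaller parameter
#' count, then lexicographically on the orders; candidates whose fit does not
#' converge are excluded (and noted in the grid).
#'
#' So that conditional likelihoods are comparable across candidates, every
#' candidate's likelihood is re-evaluated on the common conditioning sample:
#' observations after `max(d + max(p, q))` over the whole grid (for ARIMA,
#' with the innovation variance re-profiled on that window; for volatility
#' models, after the largest `max(p, q)`). Without this, candidates with more
#' lags silently drop more burn-in residuals and gain a spurious likelihood
#' advantage.
#'
#' @param x Numeric series.
#' @param grid A data frame of candidate orders: columns `p`, `d`, `q` for
#'   `model_kind = "arima"`, or `p`, `q` for a volatility family. See
#'   [order_grid()] for a helper.
#' @param model_kind `"arima"` or one of the volatility families.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param ... Passed to the fitter.
#' @return An object of class `ecg_selection`: `grid` (tibble with `loglik`,
#'   `k`, `n`, `value`, `converged` per candidate), `chosen` (named list of
#'   orders), `criterion`.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = c(0.5, 0.2)), n = 2000))
#' sel <- select_orders(x, order_grid(p = 0:2, d = 0, q = 0:1))
#' sel$chosen
#' @export
select_orders <- function(x, grid, model_kind = c("arima", "arch", "garch",
                                                  "gjr", "egarch"),
                          criterion = c("bic", "aic"), ...) {
  model_kind <- match.arg(model_kind)
  criterion <- match.arg(criterion)
  x <- assert_numeric_vector(x, "x")
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("`grid` must contain at least one candidate.")
  is_arima <- model_kind == "arima"
  need <- if (is_arima) c("p", "d", "q") else c("p", "q")
  if (!all(need %in% names(grid))) {
    abort(sprintf("`grid` must have columns %s.", paste(need, collapse = ", ")))
  }
  c0 <- if (is_arima) max(grid$d + pmax(grid$p, grid$q)) else max(pmax(grid$p, grid$q))
  res <- purrr::pmap(grid[need], function(p, d = NULL, q) {
    fit <- tryCatch({
      if (is_arima) fit_arima(x, order = c(p, d, q), ...)
      else fit_volatility(x, vol_orders(model_kind, p = p, q = q), ...)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble(k = NA_integer_, n = NA_integer_, loglik = NA_real_,
                    value = NA_real_, converged = FALSE,
                    note = conditionMessage(fit)))
    }
    k <- fit$n_params
    if (is_arima) {
      # common window, variance re-profiled on it
      eps <- fit$residuals
      idx <- (c0 - d + 1):length(eps)
      s2 <- mean(eps[idx]^2)
      n_eff <- length(idx)
      ll <- -0.5 * n_eff * (log(2 * pi * s2) + 1)
    } else {
      idx <- (c0 + 1):length(fit$y)
      s2p <- fit$sigma2_path[idx]
      n_eff <- length(idx)
      ll <- sum(-0.5 * (log(2 * pi) + log(s2p) + fit$y[idx]^2 / s2p))
    }
    ic <- information_criterion(criterion, k, n_eff, ll)
    tibble(k = k, n = n_eff, loglik = ll, value = ic$value,
           converged = fit$converged, note = NA_character_)
  })
  grid_out <- dplyr::bind_cols(grid[need], dplyr::bind_rows(res))
  ok <- grid_out$converged & is.finite(grid_out$value)
  if (!any(ok)) {
    abort(paste0("No candidate converged. Notes:\n",
                 paste(utils::head(grid_out$note, 10), collapse = "\n")))
  }
  cand <- grid_out[ok, ]
  ord_cols <- as.list(cand[need])
  o <- do.call(order, c(list(cand$value, cand$k), ord_cols))
  chosen <- as.list(cand[o[1], need])
  structure(list(grid = grid_out, chosen = chosen, criterion = criterion,
                 model_kind = model_kind), class = "ecg_selection")
}

#' @rdname select_orders
#' @param p,d,q Integer vectors of candidate orders; the grid is their cross
#'   product.
#' @export
order_grid <- function(p = 0:5, d = 0:2, q = 0:5) {
  tidyr::expand_grid(p = as.integer(p), d = as.integer(d), q = as.integer(q))
}

#' @export
print.ecg_selection <- function(x, ...) {
  cat(sprintf("Order selection (%s, %s) over %d candidates\n",
              x$model_kind, toupper(x$criterion), nrow(x$grid)))
  cat("  chosen:", paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Rank fitted models by log-likelihood
#'
#' Orders a set of named fits by decreasing log-likelihood (stable for equal
#' values); the top model is the maximum-likelihood choice among the
#' candidate families.
#'
#' @param fits A named list of fitted objects (`ecg_arima`, `ecg_volatility`
#'   or `ecg_composite`).
#' @return A tibble: `model`, `loglik`, `n_params`, `rank`.
#' @export
rank_by_loglik <- function(fits) {
  if (length(fits) == 0) abort("`fits` must contain at least one fit.")
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  ll <- purrr::map_dbl(fits, function(f) {
    if (inherits(f, "ecg_composite")) f$joint_loglik else f$loglik
  })
  k <- purrr::map_int(fits, function(f) as.integer(f$n_params))
  out <- tibble(model = names(fits), loglik = ll, n_params = k)
  out <- out[order(-out$loglik), ]
  out$rank <- seq_len(nrow(out))
  out
}
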