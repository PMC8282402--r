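#' Plot methods for fitted models and segment tables
#'
#' `autoplot()` methods return ggplot objects: observed vs one-step fitted
#' amplitude for mean and composite fits (with a `+/- sigma_t` conditional
#' envelope for the composite), and the conditional-standard-deviation
#' envelope over the innovations for a pure volatility fit — the
#' interpretation under which a zero-conditional-mean variance model "traces"
#' a signal.
#'
#' @param object A fitted `ecg_arima`, `ecg_volatility` or `ecg_composite`.
#' @param n_show Number of leading samples shown (default 500).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_arima <- function(object, n_show = 500, ...) {
  x <- object$x
  n <- min(n_show, length(x))
  df <- tibble(t = seq_len(n), observed = x[seq_len(n)],
               fitted = fitted_values(object)[seq_len(n)])
  df <- tidyr::pivot_longer(df, -"t", names_to = "series", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$amplitude, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "sample", y = "amplitude",
                  title = sprintf("ARIMA(%d,%d,%d) one-step fit",
                                  object$orders$p, object$orders$d, object$orders$q)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ecg_arima
#' @export
autoplot.ecg_volatility <- function(object, n_show = 500, ...) {
  n <- min(n_show, length(object$y))
  df <- tibble(t = seq_len(n), y = object$y[seq_len(n)],
               sigma = sqrt(object$sigma2_path[seq_len(n)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$sigma, ymax = .data$sigma),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "sample", y = "innovation",
                  title = sprintf("%s conditional +/- sigma envelope",
                                  toupper(object$orders$family))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ecg_arima
#' @export
autoplot.ecg_composite <- function(object, n_show = 500, ...) {
  x <- object$x
  n <- min(n_show, length(x))
  fv <- fitted_values(object)
  d <- object$arima$orders$d
  sig <- sqrt(object$sigma2_path)
  sig_full <- c(rep(sig[1], d), sig)[seq_len(n)]
  df <- tibble(t = seq_len(n), observed = x[seq_len(n)], fitted = fv[seq_len(n)],
               sigma = sig_full)
  ggplot2::ggplot(df, ggplot2::aes(.data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - .data$sigma,
                                      ymax = .data$fitted + .data$sigma),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linewidth = 0.3) +
    ggplot2::labs(x = "sample", y = "amplitude",
                  title = "Composite one-step fit with conditional envelope") +
    ggplot2::theme_minimal()
}

#' Plot a distribution comparison
#'
#' Histogram (with the Gaussian reference curve) or empirical CDF overlay for
#' the output of [distribution_compare()].
#'
#' @param comparison A list from [distribution_compare()].
#' @param type `"histogram"` or `"cdf"`.
#' @return A ggplot object.
#' @export
plot_distribution <- function(comparison, type = c("histogram", "cdf")) {
  type <- match.arg(type)
  if (type == "histogram") {
    df <- tidyr::pivot_longer(comparison$histogram, -"mid",
                              names_to = "series", values_to = "density")
    ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$density, colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "amplitude", y = "density") +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(comparison$ecdf, -"value",
                              names_to = "series", values_to = "probability")
    ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$probability,
                                     colour = .data$series)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "amplitude", y = "cumulative probability") +
      ggplot2::theme_minimal()
  }
}
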