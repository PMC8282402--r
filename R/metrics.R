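#' Per-segment prediction error metrics
#'
#' MSE, RMSE (`sqrt(MSE)` exactly), MAE and MAPE between observed and
#' predicted values. MAPE is `mean(|X - Xhat| / |X|) * 100` and is undefined
#' where the observed value is zero; by default those indices are excluded
#' and counted (`n_mape_excluded`), since raw ECG amplitudes cross zero.
#' `mape_mode = "naive"` keeps the naive division for fidelity with reports
#' that used it (zero observations then yield an infinite MAPE).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param mape_mode `"exclude"` (default) or `"naive"`.
#' @return A one-row tibble: `mse`, `rmse`, `mae`, `mape` (percent), `n`,
#'   `n_mape_excluded`.
#' @examples
#' error_metrics(c(1, 2, 4), c(2, 1, 5))$mape # 58.33...
#' @export
error_metrics <- function(observed, predicted, mape_mode = c("exclude", "naive")) {
  mape_mode <- match.arg(mape_mode)
  observed <- assert_numeric_vector(observed, "observed")
  predicted <- assert_numeric_vector(predicted, "predicted")
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  err <- observed - predicted
  mse <- mean(err^2)
  mae <- mean(abs(err))
  nz <- observed != 0
  n_excl <- sum(!nz)
  if (mape_mode == "exclude") {
    if (!any(nz)) {
      warn("MAPE undefined: every observed value is zero; reported as NA.")
      mape <- NA_real_
    } else {
      mape <- mean(abs(err[nz]) / abs(observed[nz])) * 100
    }
  } else {
    mape <- mean(abs(err) / abs(observed)) * 100
  }
  tibble(mse = mse, rmse = sqrt(mse), mae = mae, mape = mape,
         n = length(observed), n_mape_excluded = n_excl)
}

#' Aggregate per-segment metrics by label group and model
#'
#' Group means and sample (n-1 denominator) standard deviations of the four
#' error metrics, the layout of a segment-level model comparison table. A
#' group with a single segment reports a standard deviation of 0.
#'
#' @param per_segment A tibble with columns `mse`, `rmse`, `mae`, `mape` and
#'   the grouping columns.
#' @param group_by Character vector of grouping columns present in
#'   `per_segment` (default `c("label", "model")`, reduced to those present).
#' @return A tibble with one row per group: `n_segments` and
#'   `<metric>_mean` / `<metric>_sd` for each metric.
#' @export
aggregate_metrics <- function(per_segment, group_by = c("label", "model")) {
  per_segment <- as_tibble(per_segment)
  metrics <- c("mse", "rmse", "mae", "mape")
  if (!all(metrics %in% names(per_segment))) {
    abort("`per_segment` must contain columns mse, rmse, mae, mape.")
  }
  group_by <- intersect(group_by, names(per_segment))
  sd0 <- function(v) if (sum(is.finite(v)) < 2) 0 else sd(v, na.rm = TRUE)
  out <- per_segment |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd0(.x)),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
  out
}
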