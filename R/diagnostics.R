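#' Moment summary of a sample
#'
#' Mean, standard deviation, skewness and kurtosis with population (biased)
#' estimators: `kurtosis = E[(x - mu)^4] / sigma^4` and
#' `skewness = E[(x - mu)^3] / sigma^3`, no small-sample correction. A
#' kurtosis above 3 (the Gaussian value) marks a heavy-tailed, volatile
#' series; every sample has kurtosis >= 1, with equality for a symmetric
#' two-point distribution.
#'
#' @param x Numeric vector, length >= 4, non-constant.
#' @return A one-row tibble: `mean`, `sd`, `skewness`, `kurtosis`, `n`.
#' @examples
#' moment_summary(rep(c(-1, 1), 50)) # kurtosis exactly 1
#' @export
moment_summary <- function(x) {
  x <- assert_numeric_vector(x, "x", min_length = 4L)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) abort("Moments undefined for a constant sample.")
  tibble(
    mean = mu, sd = sqrt(s2),
    skewness = mean((x - mu)^3) / s2^1.5,
    kurtosis = mean((x - mu)^4) / s2^2,
    n = length(x)
  )
}

#' Engle's ARCH-LM test for conditional heteroskedasticity
#'
#' Lagrange-multiplier test of the null that no ARCH/GARCH effect is present:
#' the squared, demeaned residuals are regressed on a constant and their first
#' `lags` lags; the statistic `n_eff * R^2` is asymptotically chi-square with
#' `lags` degrees of freedom. The null is rejected when the statistic exceeds
#' the upper-`alpha` chi-square critical value (3.8415 at the default one lag
#' and 5% level). The statistic is invariant to rescaling of the residuals.
#'
#' @param residuals Numeric series (a segment or model residuals).
#' @param lags Number of lags in the auxiliary regression (default 1).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `name`, `statistic`, `threshold`, `p_value`,
#'   `decision` (1 = ARCH effect detected), `alpha`, `lags`, `status`.
#' @export
engle_arch_test <- function(residuals, lags = 1L, alpha = 0.05) {
  x <- assert_numeric_vector(residuals, "residuals", min_length = 4L)
  lags <- assert_count(lags, "lags", lower = 1L)
  alpha <- assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (length(x) < lags + 3L) abort("Series too short for the requested lag order.")
  u2 <- (x - mean(x))^2
  E <- stats::embed(u2, lags + 1L)
  yv <- E[, 1]
  X <- cbind(1, E[, -1, drop = FALSE])
  n_eff <- length(yv)
  sst <- sum((yv - mean(yv))^2)
  threshold <- qchisq(1 - alpha, df = lags)
  if (sst <= 0) {
    warn("Degenerate auxiliary regression: squared residuals are constant.")
    return(tibble(name = "engle_arch_lm", statistic = 0, threshold = threshold,
                  p_value = 1, decision = 0L, alpha = alpha, lags = lags,
                  status = "degenerate"))
  }
  fit <- stats::lm.fit(X, yv)
  ssr <- sum(fit$residuals^2)
  stat <- n_eff * (1 - ssr / sst)
  tibble(name = "engle_arch_lm", statistic = stat, threshold = threshold,
         p_value = pchisq(stat, df = lags, lower.tail = FALSE),
         decision = as.integer(stat > threshold), alpha = alpha, lags = lags,
         status = "ok")
}

#' Paired Wilcoxon signed-rank test with tie adjustment
#'
#' Nonparametric test that two paired samples come from the same population.
#' Zero differences are dropped; absolute differences are ranked with midranks
#' for ties; the statistic `W` is the sum of the ranks of the positive
#' differences, and the normal approximation
#' `z = (W - n(n+1)/4) / sqrt((n(n+1)(2n+1) - tieadj) / 24)` is used with
#' `tieadj = sum(t^3 - t) / 2` over groups of `t` tied absolute differences
#' (equivalently, the classical tie-corrected variance). The two-sided
#' p-value comes from the standard normal; no continuity correction is
#' applied.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `name`, `statistic` (W), `z`, `p_value`,
#'   `decision`, `alpha`, `n` (nonzero differences), `tieadj`.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05) {
  x <- assert_numeric_vector(x, "x"); y <- assert_numeric_vector(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  alpha <- assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All paired differences are zero: the signed-rank test is undefined.")
  r <- rank(abs(d)) # midranks for ties
  W <- sum(r[d > 0])
  tie_sizes <- table(abs(d))
  tieadj <- sum(tie_sizes^3 - tie_sizes) / 2
  mu_w <- n * (n + 1) / 4
  var_w <- (n * (n + 1) * (2 * n + 1) - tieadj) / 24
  if (var_w <= 0) abort("Zero variance: all differences are tied at one value.")
  z <- (W - mu_w) / sqrt(var_w)
  p <- min(1, 2 * pnorm(-abs(z)))
  tibble(name = "wilcoxon_signed_rank", statistic = W, z = z, p_value = p,
         decision = as.integer(p < alpha), alpha = alpha, n = n, tieadj = tieadj)
}

#' Compare two sample distributions
#'
#' Histogram counts over shared bin edges spanning the pooled range, a
#' Gaussian reference density using the first sample's mean and standard
#' deviation, both empirical CDFs, and the Kolmogorov-Smirnov distance (the
#' maximum ECDF gap) as a numeric summary of the visual histogram/CDF check.
#'
#' @param x,y Numeric samples (non-empty).
#' @param bins Number of histogram bins (>= 2, default 50).
#' @return A list with `histogram` (tibble: `mid`, `density_x`, `density_y`,
#'   `gaussian_reference`), `ecdf` (tibble: `value`, `ecdf_x`, `ecdf_y`),
#'   and `ks_distance`.
#' @export
distribution_compare <- function(x, y, bins = 50L) {
  x <- assert_numeric_vector(x, "x"); y <- assert_numeric_vector(y, "y")
  bins <- assert_count(bins, "bins", lower = 2L)
  rng <- range(c(x, y))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  hx <- graphics::hist(x, breaks = edges, plot = FALSE)
  hy <- graphics::hist(y, breaks = edges, plot = FALSE)
  mu <- mean(x); s <- sd(x)
  pooled <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
  list(
    histogram = tibble(mid = hx$mids, density_x = hx$density,
                       density_y = hy$density,
                       gaussian_reference = stats::dnorm(hx$mids, mu, s)),
    ecdf = tibble(value = pooled, ecdf_x = Fx(pooled), ecdf_y = Fy(pooled)),
    ks_distance = max(abs(Fx(pooled) - Fy(pooled)))
  )
}

#' Run the heteroskedasticity diagnostic battery over segments
#'
#' For each segment: moment summary and Engle's ARCH-LM test; when a
#' same-length reference series simulated from a fitted GARCH-family model is
#' supplied, also the paired (by sample index) Wilcoxon signed-rank test and
#' the ECDF comparison against it. This is the pre-modelling volatility
#' screen: heavy tails (kurtosis > 3), skewness, and a significant ARCH-LM
#' statistic justify a conditional-variance model.
#'
#' @param segments A segment tibble ([segment_signal()] /
#'   [simulate_ecg_segments()]).
#' @param reference Optional reference series: a numeric vector (recycled for
#'   all segments) or a list of vectors, each the length of the matching
#'   segment.
#' @param lags,alpha Engle test controls.
#' @return A tibble, one row per segment: identifiers plus `mean`, `sd`,
#'   `skewness`, `kurtosis`, `engle_stat`, `engle_p`, `engle_h` and (with a
#'   reference) `wilcoxon_stat`, `wilcoxon_p`, `wilcoxon_h`, `ks_distance`.
#' @export
run_battery <- function(segments, reference = NULL, lags = 1L, alpha = 0.05) {
  if (!is.data.frame(segments) || !"samples" %in% names(segments)) {
    abort("`segments` must be a segment tibble with a `samples` list-column.")
  }
  n_seg <- nrow(segments)
  refs <- if (is.null(reference)) NULL
    else if (is.numeric(reference)) replicate(n_seg, reference, simplify = FALSE)
    else reference
  rows <- purrr::map(seq_len(n_seg), function(i) {
    x <- as.numeric(segments$samples[[i]])
    mo <- moment_summary(x)
    en <- engle_arch_test(x, lags = lags, alpha = alpha)
    out <- tibble(
      mean = mo$mean, sd = mo$sd, skewness = mo$skewness, kurtosis = mo$kurtosis,
      engle_stat = en$statistic, engle_p = en$p_value, engle_h = en$decision
    )
    if (!is.null(refs)) {
      w <- wilcoxon_signed_rank(x, refs[[i]], alpha = alpha)
      dc <- distribution_compare(x, refs[[i]])
      out$wilcoxon_stat <- w$statistic
      out$wilcoxon_p <- w$p_value
      out$wilcoxon_h <- w$decision
      out$ks_distance <- dc$ks_distance
    }
    out
  })
  ids <- dplyr::select(as_tibble(segments),
                       dplyr::any_of(c("record_id", "index", "label")))
  dplyr::bind_cols(ids, dplyr::bind_rows(rows))
}
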