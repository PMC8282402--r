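test_that("moment summary uses population estimators with known closed forms", {
  mo <- moment_summary(rep(c(-1, 1), 50))
  expect_equal(mo$kurtosis, 1)
  expect_equal(mo$skewness, 0)
  expect_equal(mo$sd, 1)

  z <- withr::with_seed(101, rnorm(1e5))
  expect_equal(moment_summary(z)$kurtosis, 3, tolerance = 0.1 / 3)

  g <- simulate_volatility(vol_orders("garch", 1, 1), vol_params(0.1, 0.3, 0.6),
                           n = 6000, seed = 102)$y
  expect_gt(moment_summary(g)$kurtosis, 3)

  expect_error(moment_summary(rep(1, 10)), "constant")
  # kurtosis is bounded below by 1 on any sample
  for (s in 1:10) {
    x <- withr::with_seed(s, sample(c(rnorm(20), runif(5))))
    expect_gte(moment_summary(x)$kurtosis, 1)
  }
})

test_that("the ARCH-LM threshold is the chi-square critical value 3.8415", {
  r <- engle_arch_test(withr::with_seed(1, rnorm(100)), lags = 1, alpha = 0.05)
  expect_equal(round(r$threshold, 4), 3.8415)
  expect_equal(r$threshold, qchisq(0.95, 1))
})

test_that("the ARCH-LM statistic is scale-free and detects ARCH effects", {
  x <- withr::with_seed(111, rnorm(1000))
  a <- engle_arch_test(x)
  b <- engle_arch_test(1000 * x)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)

  for (s in 1:5) {
    y <- simulate_volatility(vol_orders("arch", 0, 1), vol_params(0.5, 0.5),
                             n = 6000, seed = s)$y
    expect_equal(engle_arch_test(y)$decision, 1L)
  }

  const <- rep(2, 100)
  expect_warning(r0 <- engle_arch_test(const), "Degenerate")
  expect_equal(r0$decision, 0L)
  expect_equal(r0$p_value, 1)
})

test_that("ARCH-LM size is near nominal on white noise", {
  rej <- vapply(1:400, function(s) {
    engle_arch_test(withr::with_seed(2000 + s, rnorm(500)))$decision
  }, 0L)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("signed-rank extreme case gives the maximal statistic", {
  x <- withr::with_seed(121, rnorm(50))
  r <- wilcoxon_signed_rank(x + 1, x)
  expect_equal(r$statistic, 50 * 51 / 2)
  expect_equal(r$decision, 1L)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
})

test_that("signed-rank z matches the exhaustive enumeration null", {
  # with ties: midranks and the printed tie adjustment
  for (case in list(c(0.5, 1.2, 1.2, 2.0, 3.1, 3.1),
                    c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                    c(0.2, 0.2, 0.2, 1.4, 2.2, 2.8, 2.8))) {
    wnull <- enumerate_signed_rank(case)
    mu_null <- mean(wnull)
    var_null <- mean((wnull - mu_null)^2) # population variance of the exact null
    x <- case * withr::with_seed(round(sum(case) * 100),
                                 sample(c(-1, 1), length(case), TRUE))
    r <- wilcoxon_signed_rank(x, rep(0, length(case)))
    # the normal approximation's centring and tie-adjusted variance equal the
    # exact enumeration null's mean and variance
    expect_equal(mu_null, length(case) * (length(case) + 1) / 4)
    expect_equal(r$z, (r$statistic - mu_null) / sqrt(var_null), tolerance = 1e-12)
  }
})

test_that("signed-rank normal p tracks exact enumeration in the rejection band", {
  # the no-continuity-correction normal p approximates the exact two-sided
  # mid-p; over every attainable statistic with exact p <= 0.2 the gap stays
  # below 0.01 once n >= 8 (with or without ties)
  for (abs_d in list(c(0.7, 1.1, 1.9, 2.4, 3.0, 3.6, 4.2, 5.5, 6.0, 7.7),
                     c(1, 2, 2, 3, 4, 4, 4, 5))) {
    n <- length(abs_d)
    wnull <- enumerate_signed_rank(abs_d)
    expect_equal(mean(wnull), n * (n + 1) / 4) # exact null mean
    tot <- n * (n + 1) / 2
    worst <- 0
    for (w in unique(wnull)) {
      hi <- max(w, tot - w)
      p_mid <- min(1, 2 * (mean(wnull > hi) + 0.5 * mean(wnull == hi)))
      # realise this statistic through an actual paired sample
      signs <- rep(-1, n)
      take <- which(cumsum(sort(rank(abs_d), decreasing = TRUE)) <= hi)
      signs[order(rank(abs_d), decreasing = TRUE)[take]] <- 1
      r <- wilcoxon_signed_rank(abs_d * signs, rep(0, n))
      if (r$statistic == hi && p_mid <= 0.2) {
        worst <- max(worst, abs(r$p_value - p_mid))
      }
    }
    expect_lt(worst, 0.01)
  }
})

test_that("signed-rank size is near nominal on symmetric paired noise", {
  rej <- vapply(1:400, function(s) {
    d <- withr::with_seed(3000 + s, rnorm(50))
    wilcoxon_signed_rank(d, rep(0, 50))$decision
  }, 0L)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("distribution comparison measures ECDF distance sensibly", {
  x <- withr::with_seed(131, rnorm(4000))
  self <- distribution_compare(x, x)
  expect_equal(self$ks_distance, 0)

  z <- withr::with_seed(132, rnorm(20000))
  ab <- distribution_compare(z[1:10000], z[10001:20000])
  expect_lt(ab$ks_distance, 0.02)

  g <- simulate_volatility(vol_orders("garch", 1, 1), vol_params(0.05, 0.45, 0.5),
                           n = 10000, seed = 133)$y
  gauss <- withr::with_seed(134, rnorm(10000, 0, sd(g)))
  heavy <- distribution_compare(g, gauss)
  expect_gt(heavy$ks_distance, ab$ks_distance)
  expect_error(distribution_compare(x, x, bins = 1), "bins")
})

test_that("the battery flags simulated apnea-like segments and spares controls", {
  segs <- simulate_ecg_segments("apnea_like", n_segments = 3, seed = 141)
  rep <- run_battery(segs)
  expect_true(all(rep$kurtosis > 3))
  expect_true(all(rep$engle_h == 1L))
  expect_equal(rep$label, rep("apnea", 3))

  ctrl <- simulate_ecg_segments("homoskedastic_control", n_segments = 30,
                                segment_length = 1500, seed = 142)
  crep <- run_battery(ctrl)
  expect_lte(mean(crep$engle_h), 0.2)
})

test_that("battery reports with a reference round-trip through JSON", {
  segs <- simulate_ecg_segments("normal_like", n_segments = 2,
                                segment_length = 1200, seed = 151)
  ref <- simulate_volatility(vol_orders("egarch", 1, 1), egarch_truth(),
                             n = 1200, seed = 152)$y
  rep <- run_battery(segs, reference = ref)
  expect_true(all(c("wilcoxon_p", "ks_distance") %in% names(rep)))
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep, tmp, digits = NA, dataframe = "columns")
  back <- jsonlite::fromJSON(tmp)
  expect_equal(back$kurtosis, rep$kurtosis)
  expect_equal(back$wilcoxon_p, rep$wilcoxon_p)
})
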