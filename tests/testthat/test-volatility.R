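test_that("GARCH and GJR variance recursions match hand arithmetic", {
  o <- vol_orders("garch", 1, 1)
  p <- vol_params(0.1, 0.2, 0.7)
  s2 <- variance_path(c(1, 0), o, p, sigma2_init = 1)
  expect_equal(as.numeric(s2)[2], 0.1 + 0.2 * 1 + 0.7 * 1) # = 1.0
  s2b <- variance_path(c(0, 0), o, p, sigma2_init = 1)
  expect_equal(as.numeric(s2b)[2], 0.8)
  expect_true(attr(s2, "valid"))

  og <- vol_orders("gjr", 1, 1)
  pg <- vol_params(0.1, 0.2, 0.7, gamma = 0.1)
  up <- variance_path(c(1, 0), og, pg, sigma2_init = 1)
  dn <- variance_path(c(-1, 0), og, pg, sigma2_init = 1)
  expect_equal(as.numeric(dn)[2] - as.numeric(up)[2], 0.1) # indicator adds gamma * y^2
})

test_that("GJR with zero asymmetry reproduces GARCH exactly, term for term", {
  y <- simulate_volatility(vol_orders("garch", 1, 1), vol_params(0.1, 0.2, 0.7),
                           n = 2000, seed = 31)$y
  o_g <- vol_orders("garch", 1, 1)
  o_j <- vol_orders("gjr", 1, 1)
  p_g <- vol_params(0.05, 0.15, 0.75)
  p_j <- vol_params(0.05, 0.15, 0.75, gamma = 0)
  expect_identical(as.numeric(variance_path(y, o_g, p_g)),
                   as.numeric(variance_path(y, o_j, p_j)))
  expect_identical(volatility_loglik(y, o_g, p_g), volatility_loglik(y, o_j, p_j))
})

test_that("the EGARCH shock response has the printed closed form", {
  expect_equal(egarch_g(0, theta = 0.3, lambda = 0.5), -0.5 * sqrt(2 / pi))
  z <- seq(-3, 3, by = 0.1)
  expect_equal(egarch_g(z, 0, 0.4), egarch_g(-z, 0, 0.4)) # symmetric when theta = 0
  zz <- withr::with_seed(41, rnorm(1e6))
  g <- egarch_g(zz, theta = -0.1, lambda = 0.2)
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g)), 3 * se) # E g(Z) = 0 under the standard normal
})

test_that("volatility likelihood matches the Gaussian sum and scaling identity", {
  o <- vol_orders("arch", 0, 1)
  p0 <- vol_params(1, 0)
  # constant unit variance on zeros: standard-normal log densities over the
  # conditioning window t > max(p, q)
  expect_equal(volatility_loglik(c(0, 0, 0), o, p0, sigma2_init = 1),
               -(2 / 2) * log(2 * pi))
  # scaling y by c and alpha0 by c^2 (pure ARCH) shifts the loglik by -n log c
  y <- withr::with_seed(42, rnorm(400))
  pa <- vol_params(0.5, 0.4)
  ll1 <- volatility_loglik(y, o, pa)
  cc <- 3
  pc <- vol_params(0.5 * cc^2, 0.4)
  ll2 <- volatility_loglik(cc * y, o, pc)
  n_eff <- length(y) - 1
  expect_equal(ll2, ll1 - n_eff * log(cc), tolerance = 1e-10)
})

test_that("variance paths stay positive for valid parameters", {
  for (s in 1:10) {
    y <- withr::with_seed(s, rnorm(300, sd = runif(1, 0.1, 5)))
    a <- runif(1, 0.01, 0.4); b <- runif(1, 0, 0.9 - a)
    s2 <- variance_path(y, vol_orders("garch", 1, 1), vol_params(0.05, a, b))
    expect_true(attr(s2, "valid"))
    expect_true(all(s2 > 0))
    pe <- vol_params(-0.1, 1, 0.8, theta = -0.2, lambda = 0.3)
    s2e <- variance_path(y, vol_orders("egarch", 1, 1), pe)
    expect_true(all(s2e > 0))
  }
})

test_that("quasi-MLE recovers GARCH, GJR and EGARCH generating parameters", {
  sg <- simulate_volatility(vol_orders("garch", 1, 1), vol_params(0.1, 0.2, 0.7),
                            n = 20000, seed = 51)
  fg <- fit_volatility(sg$y, vol_orders("garch", 1, 1))
  expect_lt(abs(fg$params$alpha0 - 0.1), 0.05)
  expect_lt(abs(fg$params$alpha - 0.2), 0.05)
  expect_lt(abs(fg$params$beta - 0.7), 0.05)
  expect_true(fg$converged)

  pj <- vol_params(0.1, 0.1, 0.7, gamma = 0.2)
  sj <- simulate_volatility(vol_orders("gjr", 1, 1), pj, n = 20000, seed = 52)
  fj <- fit_volatility(sj$y, vol_orders("gjr", 1, 1))
  expect_lt(max(abs(unlist(fj$params) - unlist(pj))), 0.05)

  se <- simulate_volatility(vol_orders("egarch", 1, 1), egarch_truth(),
                            n = 20000, seed = 53)
  fe <- fit_volatility(se$y, vol_orders("egarch", 1, 1))
  expect_lt(fe$params$theta, 0) # sign recovered
  expect_lt(abs(fe$params$beta - 0.9), 0.05)
  expect_lt(abs(fe$params$lambda - 0.2), 0.05)
  # likelihood at the truth never beats the fitted optimum
  expect_gte(fe$loglik, volatility_loglik(se$y, vol_orders("egarch", 1, 1),
                                          egarch_truth()))
})

test_that("i.i.d. Gaussian input yields a near-degenerate GARCH fit", {
  y <- withr::with_seed(61, rnorm(20000, sd = 1.5))
  f <- fit_volatility(y, vol_orders("garch", 1, 1))
  pers <- f$params$alpha + f$params$beta
  expect_lt(pers, 0.2)
  expect_lt(abs(f$params$alpha0 - var(y) * (1 - pers)), 0.1)
})

test_that("simulated processes have the implied moments and heavy tails", {
  o <- vol_orders("garch", 1, 1)
  sim <- simulate_volatility(o, vol_params(0.1, 0.2, 0.7), n = 20000, seed = 71)
  expect_equal(var(sim$y), 0.1 / (1 - 0.9), tolerance = 0.15) # unconditional variance 1
  expect_identical(sim, simulate_volatility(o, vol_params(0.1, 0.2, 0.7),
                                            n = 20000, seed = 71))
  # degenerate case: i.i.d. N(0, alpha0)
  s0 <- simulate_volatility(o, vol_params(2, 0, 0), n = 20000, seed = 72)
  expect_equal(var(s0$y), 2, tolerance = 0.1)
  expect_equal(unique(s0$sigma2), 2)
  # excess kurtosis from ARCH dynamics on every seed
  kurts <- vapply(1:10, function(s) {
    moment_summary(simulate_volatility(o, vol_params(0.1, 0.3, 0.6),
                                       n = 6000, seed = s)$y)$kurtosis
  }, 0)
  expect_true(all(kurts > 3))
  expect_error(simulate_volatility(o, vol_params(0.1, 0.5, 0.6), 100), "Explosive")
})

test_that("volatility orders and parameters are validated", {
  expect_error(vol_orders("arch", p = 1), "p = 0")
  expect_error(vol_orders("garch", q = 0), ">= 1")
  expect_error(variance_path(rnorm(10), vol_orders("garch", 1, 1),
                             vol_params(-1, 0.1, 0.2)), "positive")
  expect_error(variance_path(rnorm(10), vol_orders("garch", 1, 1),
                             vol_params(1, 0.1, 0.2, gamma = 0.1)), "GJR")
  expect_error(fit_volatility(rnorm(10), vol_orders("garch", 1, 1)), "too short")
})
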