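infer_vol_family <- function(params, p, q) {
  if (!is.null(params$theta) || !is.null(params$lambda)) "egarch"
  else if (!is.null(params$gamma)) "gjr"
  else if (p > 0) "garch" else "arch"
}

#' Simulate a composite mean + conditional-variance process
#'
#' Draws innovations from a volatility recursion (EGARCH by default), feeds
#' them through an ARMA recursion, and integrates `d` times (with zero
#' initial values), producing a series with known mean and variance ground
#' truth. Warm-up samples for both recursions are discarded. With all
#' volatility dynamics zeroed the output reduces to a plain Gaussian ARIMA
#' simulation driven by the same seed stream.
#'
#' @param mean_params List with `ar` (vector), `ma` (vector), `d` (0..2).
#' @param vol_params A [vol_params()]; the family is inferred from which
#'   coefficients are present (`theta`/`lambda` imply EGARCH, `gamma` GJR).
#' @param n Output length (the differenced noise has length `n - d`).
#' @param seed Integer seed.
#' @param burn_in Warm-up samples discarded from both recursions (default 500).
#' @return A list: `x` (length `n`), `sigma2` (conditional variance of the
#'   innovations, length `n - d`), and `truth` (all generating parameters and
#'   the seed).
#' @export
simulate_composite <- function(mean_params, vol_params, n, seed = 1L,
                               burn_in = 500L) {
  n <- assert_count(n, "n", lower = 4L)
  ar <- as.numeric(mean_params$ar %||% numeric(0))
  ma <- as.numeric(mean_params$ma %||% numeric(0))
  d <- assert_count(mean_params$d %||% 0L, "d")
  if (d > 2) abort("`mean_params$d` must be 0, 1 or 2.")
  if (length(ar) && all(ar == 0)) ar <- numeric(0)
  if (length(ma) && all(ma == 0)) ma <- numeric(0)
  if (length(ar) > 0) {
    pac <- ar_to_pacf(ar)
    if (anyNA(pac) || any(abs(pac) >= 1)) abort("Explosive AR parameters.")
  }
  p_v <- length(vol_params$beta); q_v <- max(1L, length(vol_params$alpha))
  family <- infer_vol_family(vol_params, p_v, q_v)
  orders <- vol_orders(family, p = if (family == "arch") 0L else p_v, q = q_v)
  nd <- n - d
  if (nd < 2) abort("`n` too small for the requested differencing order.")
  total <- nd + burn_in
  innov <- simulate_volatility(orders, vol_params, n = total, seed = seed,
                               burn_in = burn_in)
  y <- innov$y
  u <- y
  for (k in seq_along(ma)) {
    u[(k + 1):total] <- u[(k + 1):total] + ma[k] * y[1:(total - k)]
  }
  w <- if (length(ar) > 0) as.numeric(filter(u, ar, method = "recursive")) else u
  keep <- (burn_in + 1):total
  x <- undifference(w[keep], d, initial_values = rep(0, d))
  list(
    x = as.numeric(x),
    sigma2 = innov$sigma2[keep],
    truth = list(mean_params = list(ar = ar, ma = ma, d = d),
                 vol_params = vol_params, vol_orders = orders,
                 n = n, seed = seed, burn_in = burn_in)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

regime_scenario <- function(regime, config_path = NULL) {
  cfg_path <- config_path %||% default_regime_config()
  cfg <- parse_config(cfg_path)
  if (!regime %in% names(cfg)) {
    abort(sprintf("Unknown regime '%s' (config defines: %s).", regime,
                  paste(names(cfg), collapse = ", ")))
  }
  rc <- cfg[[regime]]
  persist <- rc$egarch_persist
  beta <- if (length(persist) == 1 && persist == 0) numeric(0) else persist
  vp <- vol_params(rc$egarch_alpha0, alpha = rc$egarch_shock, beta = beta,
                   theta = rc$egarch_theta, lambda = rc$egarch_lambda)
  mp <- list(
    ar = if (all(rc$mean_ar == 0)) numeric(0) else rc$mean_ar,
    ma = if (all(rc$mean_ma == 0)) numeric(0) else rc$mean_ma,
    d = as.integer(rc$mean_d)
  )
  list(regime = regime, label = rc$label, mean_params = mp, vol_params = vp,
       baseline_amplitude = rc$baseline_amplitude, beat_rate_hz = rc$beat_rate_hz,
       beat_jitter_sd = rc$beat_jitter_sd, beat_width_s = rc$beat_width_s)
}

#' Simulate ECG-like heteroskedastic segments with known ground truth
#'
#' Generates labelled one-minute segments carrying the statistical structure
#' the diagnostic battery targets: a quasi-periodic train of Gaussian-bump
#' "beats" (jittered ~1 Hz intervals) plus a composite ARIMA-EGARCH noise
#' process. The `"apnea_like"` regime uses stronger EGARCH persistence and
#' shock response than `"normal_like"`; the `"homoskedastic_control"` regime
#' zeroes all dynamics and the beat baseline, so its segments are i.i.d.
#' Gaussian — the exact null of the heteroskedasticity tests. Regime
#' parameters live in a plain-text config file
#' (`system.file("extdata", "regimes.conf", package = "ecgarch")`); the
#' surrogate makes no claim of morphological fidelity.
#'
#' @param regime `"apnea_like"`, `"normal_like"` or `"homoskedastic_control"`
#'   (or any regime defined in `config_path`).
#' @param n_segments Number of segments (default 10).
#' @param segment_length Samples per segment (default 6000, i.e. one minute at
#'   100 Hz).
#' @param sampling_rate Hz (default 100).
#' @param seed Integer master seed; per-segment seeds are derived from it.
#' @param config_path Optional alternative regime config file.
#' @return A segment tibble (as from [segment_signal()]) with a `truth`
#'   list-column recording each segment's generating parameters and seeds.
#' @examples
#' segs <- simulate_ecg_segments("apnea_like", n_segments = 2, seed = 7)
#' run_battery(segs)
#' @export
simulate_ecg_segments <- function(regime, n_segments = 10, segment_length = 6000,
                                  sampling_rate = 100, seed = 1L,
                                  config_path = NULL) {
  sc <- regime_scenario(regime, config_path)
  n_segments <- assert_count(n_segments, "n_segments", lower = 1L)
  L <- assert_count(segment_length, "segment_length", lower = 64L)
  rate <- assert_scalar_number(sampling_rate, "sampling_rate", lower = 1e-9)
  seed <- assert_count(seed, "seed")
  seeds <- withr::with_seed(seed, matrix(sample.int(2147483646L, 2 * n_segments),
                                         ncol = 2))
  rows <- purrr::map(seq_len(n_segments), function(i) {
    noise <- simulate_composite(sc$mean_params, sc$vol_params, n = L,
                                seed = seeds[i, 1])
    x <- noise$x
    if (sc$baseline_amplitude > 0 && sc$beat_rate_hz > 0) {
      x <- x + beat_baseline(L, rate, sc$beat_rate_hz, sc$beat_jitter_sd,
                             sc$beat_width_s, sc$baseline_amplitude,
                             seed = seeds[i, 2])
    }
    list(samples = x,
         truth = c(noise$truth, list(regime = sc$regime,
                                     baseline_seed = seeds[i, 2])))
  })
  tibble(
    record_id = sc$regime,
    index = seq_len(n_segments) - 1L,
    label = sc$label,
    sampling_rate = rate,
    n = as.integer(L),
    samples = purrr::map(rows, "samples"),
    truth = purrr::map(rows, "truth")
  )
}

# Quasi-periodic Gaussian-bump beat train.
beat_baseline <- function(L, rate, beat_rate, jitter_sd, width_s, amplitude, seed) {
  tt <- (seq_len(L) - 1) / rate
  dur <- L / rate
  n_beats <- ceiling(dur * beat_rate) + 2L
  intervals <- withr::with_seed(seed,
    pmax(0.3, rnorm(n_beats, mean = 1 / beat_rate, sd = jitter_sd)))
  beats <- cumsum(c(0.3, intervals))
  beats <- beats[beats < dur + 0.5]
  base <- numeric(L)
  for (bt in beats) {
    lo <- max(1, floor((bt - 5 * width_s) * rate)); hi <- min(L, ceiling((bt + 5 * width_s) * rate))
    if (lo <= hi) {
      idx <- lo:hi
      base[idx] <- base[idx] + amplitude * exp(-(tt[idx] - bt)^2 / (2 * width_s^2))
    }
  }
  base
}

#' Write and read a fixture set of segments
#'
#' `write_fixture_set()` writes one amplitude CSV per segment (the
#' [read_signal_csv()] dialect) plus a `manifest.json` recording file names,
#' labels, seeds and, when present, the generating truth parameters;
#' `read_fixture_set()` reads the set back. Reading reproduces the written
#' sample values exactly, and regenerating with the manifest's seeds
#' reproduces the files byte-identically.
#'
#' @param segments A segment tibble.
#' @param out_dir Output directory (created if needed).
#' @return `write_fixture_set()`: the manifest path, invisibly.
#'   `read_fixture_set()`: a segment tibble.
#' @export
write_fixture_set <- function(segments, out_dir) {
  if (!is.data.frame(segments) || !"samples" %in% names(segments)) {
    abort("`segments` must be a segment tibble.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    files[i] <- sprintf("%s_%04d.csv", segments$record_id[i], segments$index[i])
    sig <- ecg_signal(as.numeric(segments$samples[[i]]),
                      segments$sampling_rate[i], segments$record_id[i])
    write_signal_csv(sig, file.path(out_dir, files[i]))
  }
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else v
  }
  manifest <- list(
    files = files,
    record_id = segments$record_id,
    index = segments$index,
    label = segments$label,
    sampling_rate = segments$sampling_rate,
    n = segments$n,
    truth = if ("truth" %in% names(segments)) lapply(segments$truth, strip)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fixture_set
#' @param dir Directory containing `manifest.json` and the segment CSVs.
#' @export
read_fixture_set <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("No manifest.json under %s.", dir))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  samples <- purrr::map(man$files, function(f) {
    read_signal_csv(file.path(dir, f))$amplitude
  })
  tibble(
    record_id = unlist(man$record_id),
    index = as.integer(unlist(man$index)),
    label = unlist(man$label),
    sampling_rate = as.numeric(unlist(man$sampling_rate)),
    n = as.integer(unlist(man$n)),
    samples = samples
  )
}
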