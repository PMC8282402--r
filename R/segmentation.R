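#' Slice a signal into fixed-length labelled segments
#'
#' Cuts a recording into consecutive non-overlapping windows of
#' `window_seconds` (one minute by default, i.e. 6000 samples at 100 Hz).
#' Windows are half-open `[i*W, (i+1)*W)` in sample coordinates, indexed from
#' 0; a trailing partial window is dropped, never padded. Labels are assigned
#' positionally, one per window, defaulting to the signal's `minute_labels`
#' attribute (set by [read_wfdb_record()]) and otherwise to `"unknown"`; a
#' label vector shorter than the number of windows is padded with `"unknown"`.
#'
#' @param signal An [ecg_signal()].
#' @param window_seconds Window length in seconds (default 60). Must give a
#'   whole number of samples at the signal's rate.
#' @param labels Optional character vector of per-window labels
#'   (`"apnea"`, `"normal"` or `"unknown"`).
#' @return A tibble with one row per segment: `record_id`, `index` (0-based),
#'   `label`, `sampling_rate`, `n` and a `samples` list-column.
#' @examples
#' sig <- ecg_signal(rnorm(12000), sampling_rate = 100)
#' segment_signal(sig) # 2 segments of 6000 samples
#' @export
segment_signal <- function(signal, window_seconds = 60, labels = NULL) {
  if (!inherits(signal, "ecg_signal")) abort("`signal` must be an `ecg_signal`.")
  window_seconds <- assert_scalar_number(window_seconds, "window_seconds", lower = 1e-9)
  rate <- sampling_rate(signal)
  w_exact <- window_seconds * rate
  w <- round(w_exact)
  if (w < 1 || abs(w_exact - w) > 1e-8) {
    abort(sprintf("`window_seconds` (%g s at %g Hz) is not a whole number of samples.",
                  window_seconds, rate))
  }
  x <- signal$amplitude
  n_seg <- floor(length(x) / w)
  if (is.null(labels)) labels <- attr(signal, "minute_labels")
  if (is.null(labels)) labels <- character(0)
  labels <- as.character(labels)
  lab <- rep("unknown", n_seg)
  k <- min(length(labels), n_seg)
  if (k > 0) lab[seq_len(k)] <- labels[seq_len(k)]
  bad <- setdiff(unique(lab), c("apnea", "normal", "unknown"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown label(s): %s (use 'apnea', 'normal' or 'unknown').",
                  paste(bad, collapse = ", ")))
  }
  tibble(
    record_id = record_id(signal),
    index = seq_len(n_seg) - 1L,
    label = lab,
    sampling_rate = rate,
    n = as.integer(w),
    samples = lapply(seq_len(n_seg), function(i) x[((i - 1L) * w + 1L):(i * w)])
  )
}

#' Randomly split segments into estimation and evaluation halves
#'
#' Draws a seed-deterministic random split of a segment table, marking a
#' `fraction` of the segments (round-half-up) as the `"train"` set used for
#' model-order estimation and the remainder as `"eval"`. The two sets are
#' disjoint and jointly cover every segment.
#'
#' @param segments A segment tibble from [segment_signal()] (any data frame
#'   with one row per segment works).
#' @param fraction Fraction assigned to the training side, in (0, 1);
#'   default 0.5.
#' @param seed Integer seed making the split reproducible.
#' @return The input with a `role` column (`"train"`/`"eval"`) added; the seed
#'   is recorded in the `split_seed` attribute.
#' @export
split_segments <- function(segments, fraction = 0.5, seed = 1L) {
  if (!is.data.frame(segments) || nrow(segments) < 2) {
    abort("`segments` must be a data frame with at least 2 rows.")
  }
  fraction <- assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie strictly in (0, 1).")
  seed <- assert_count(seed, "seed")
  n <- nrow(segments)
  n_train <- as.integer(floor(fraction * n + 0.5)) # round half up
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  role <- rep("eval", n)
  role[idx] <- "train"
  out <- dplyr::mutate(as_tibble(segments), role = role)
  attr(out, "split_seed") <- seed
  out
}
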