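#' Construct an ECG signal object
#'
#' A signal is a tibble with one row per sample (columns `sample`, a 0-based
#' index, and `amplitude`), carrying the sampling rate and a record identifier
#' as attributes. All pipeline inputs flow through this container.
#'
#' @param samples Numeric vector of amplitudes (signal units, e.g. mV). Must be
#'   non-empty and finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param record_id Character identifier for the recording.
#' @return A tibble of class `ecg_signal` with columns `sample` and
#'   `amplitude`, and attributes `sampling_rate` and `record_id`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 2 * pi, length.out = 200)), sampling_rate = 100)
#' sampling_rate(sig)
#' @export
ecg_signal <- function(samples, sampling_rate, record_id = "signal") {
  samples <- assert_numeric_vector(samples, "samples")
  sampling_rate <- assert_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  out <- tibble(sample = seq_along(samples) - 1L, amplitude = samples)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "record_id") <- as.character(record_id)[1]
  class(out) <- c("ecg_signal", class(out))
  out
}

#' @rdname ecg_signal
#' @param x An `ecg_signal`.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname ecg_signal
#' @export
record_id <- function(x) attr(x, "record_id")

signal_samples <- function(x) {
  if (inherits(x, "ecg_signal")) x$amplitude else assert_numeric_vector(x, "signal")
}

#' Read and write single-column amplitude CSV files
#'
#' The on-disk dialect is one metadata header line `# sampling_rate_hz=<value>`
#' followed by one amplitude per line ("." decimal separator, UTF-8). This is
#' the plain-text interchange format used by the fixture generator and the
#' command-line interface.
#'
#' @param path File path.
#' @param sampling_rate_override Optional sampling rate (Hz) taking precedence
#'   over (or supplying a missing) header value.
#' @param record_id Optional record identifier; defaults to the file stem.
#' @return `read_signal_csv()` returns an [ecg_signal()].
#' @export
read_signal_csv <- function(path, sampling_rate_override = NULL, record_id = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  rate <- NULL
  header <- grepl("^#", lines)
  for (h in lines[header]) {
    m <- regmatches(h, regexec("sampling_rate_hz\\s*=\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2) rate <- as.numeric(m[2])
  }
  if (!is.null(sampling_rate_override)) {
    rate <- assert_scalar_number(sampling_rate_override, "sampling_rate_override")
  }
  if (is.null(rate) || !is.finite(rate) || rate <= 0) {
    abort("Sampling rate missing: supply a `# sampling_rate_hz=` header or `sampling_rate_override`.")
  }
  body <- lines[!header]
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric or non-finite amplitude at data row %d of %s.", bad[1], path))
  }
  if (length(vals) == 0) abort(sprintf("No samples in %s.", path))
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  ecg_signal(vals, rate, record_id)
}

#' @rdname read_signal_csv
#' @param signal An [ecg_signal()] (or numeric vector plus `sampling_rate_override`).
#' @param digits Significant digits written; the default 17 round-trips doubles
#'   exactly.
#' @export
write_signal_csv <- function(signal, path, digits = 17) {
  if (!inherits(signal, "ecg_signal")) {
    abort("`signal` must be an `ecg_signal`.")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%s", format(sampling_rate(signal), digits = 17)), con)
  writeLines(formatC(signal$amplitude, digits = digits, format = "g"), con)
  invisible(path)
}
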