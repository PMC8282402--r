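#' Read a PhysioNet WFDB record
#'
#' Minimal reader for WFDB `.hea`/`.dat` pairs covering the signal formats used
#' by the Apnea-ECG database (16-bit little-endian and packed 12-bit "212").
#' When several channels are present the first is taken. ADC counts are mapped
#' to physical units via the header's gain and baseline. If a companion
#' per-minute apnea annotation file (`<record>.apn` by default) is present, its
#' labels are attached as the attribute `minute_labels` ("apnea" / "normal",
#' padded with "unknown" past the last annotated minute); [segment_signal()]
#' picks these up automatically.
#'
#' WFDB support is an optional convenience: the rest of the package only
#' requires the CSV dialect of [read_signal_csv()].
#'
#' @param header_path Path to the `.hea` header file.
#' @param annotation_ext Extension of the per-minute annotation file to look
#'   for next to the header (default `"apn"`); set `NULL` to skip.
#' @return An [ecg_signal()]; if annotations were found, with a
#'   `minute_labels` character attribute.
#' @export
read_wfdb_record <- function(header_path, annotation_ext = "apn") {
  if (!file.exists(header_path)) abort(sprintf("Header not found: %s", header_path))
  lines <- readLines(header_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("Malformed WFDB header: need a record line and one signal line.")
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) abort("Malformed WFDB header record line.")
  record <- sub("/.*$", "", rec[1])
  nsig <- suppressWarnings(as.integer(rec[2]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", rec[3])))
  if (is.na(nsig) || nsig < 1 || is.na(fs) || fs <= 0) {
    abort("Malformed WFDB header: bad signal count or sampling frequency.")
  }
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(sig) < 2) abort("Malformed WFDB signal specification line.")
  dat_file <- sig[1]
  fmt <- sub("x.*$", "", sig[2])
  gain <- 200; baseline <- NA_real_; adc_zero <- 0
  if (length(sig) >= 3) {
    gspec <- sig[3]
    m <- regmatches(gspec, regexec("^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/.*)?$", gspec))[[1]]
    if (length(m) >= 2 && nzchar(m[2])) gain <- as.numeric(m[2])
    if (length(m) >= 4 && nzchar(m[4])) baseline <- as.numeric(m[4])
  }
  if (length(sig) >= 5) adc_zero <- suppressWarnings(as.numeric(sig[5]))
  if (is.na(adc_zero)) adc_zero <- 0
  if (is.na(baseline)) baseline <- adc_zero
  if (gain == 0) gain <- 200

  dat_path <- file.path(dirname(header_path), dat_file)
  if (!file.exists(dat_path)) abort(sprintf("WFDB data file not found: %s", dat_path))
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v, nrow = nsig)[1, ]
    },
    "212" = decode_fmt212(raw, nsig),
    abort(sprintf("Unsupported WFDB signal format '%s' (formats 16 and 212 are supported).", fmt))
  )
  out <- ecg_signal((adc - baseline) / gain, fs, record)

  if (!is.null(annotation_ext)) {
    ann_path <- file.path(dirname(header_path), paste0(record, ".", annotation_ext))
    if (file.exists(ann_path)) {
      ann <- read_wfdb_annotations(ann_path)
      n_min <- floor(length(adc) / (60 * fs))
      labels <- rep("unknown", n_min)
      minute <- floor(ann$time / (60 * fs)) + 1L
      ok <- minute >= 1L & minute <= n_min
      labels[minute[ok]] <- ann$label[ok]
      attr(out, "minute_labels") <- labels
    }
  }
  out
}

# Unpack WFDB format 212: two 12-bit two's-complement samples per 3 bytes.
decode_fmt212 <- function(raw, nsig) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1, n3, 3)]; b1 <- b[seq(2, n3, 3)]; b2 <- b[seq(3, n3, 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0F), 8)
  s2 <- b2 + bitwShiftL(bitwAnd(bitwShiftR(b1, 4), 0x0F), 8)
  v <- as.vector(rbind(s1, s2))
  v <- ifelse(v > 2047, v - 4096, v)
  matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)[1, ]
}

# MIT annotation stream: 2-byte words, type in the high 6 bits, time increment
# in the low 10 bits; SKIP (59) carries a 4-byte time, AUX (63) a byte payload,
# NUM/SUB/CHAN (60-62) no time. Apnea-ECG convention: type 8 = apneic minute,
# type 1 = normal minute.
read_wfdb_annotations <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  times <- integer(0); codes <- integer(0)
  t_cur <- 0; i <- 1L
  while (i + 1L <= length(raw)) {
    word <- raw[i] + raw[i + 1L] * 256L
    code <- bitwShiftR(word, 10)
    ival <- bitwAnd(word, 1023L)
    i <- i + 2L
    if (code == 0L && ival == 0L) break
    if (code == 59L) { # SKIP: next 4 bytes are a long time offset
      if (i + 3L > length(raw)) break
      t_cur <- t_cur + raw[i + 2L] + raw[i + 3L] * 256L +
        bitwShiftL(raw[i] + raw[i + 1L] * 256L, 16)
      i <- i + 4L
    } else if (code == 63L) { # AUX: skip payload (padded to even length)
      i <- i + ival + (ival %% 2L)
    } else if (code >= 60L) { # NUM / SUB / CHAN modifiers
      next
    } else {
      t_cur <- t_cur + ival
      times <- c(times, t_cur)
      codes <- c(codes, code)
    }
  }
  label <- ifelse(codes == 8L, "apnea", ifelse(codes == 1L, "normal", "unknown"))
  tibble(time = times, code = codes, label = label)
}
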