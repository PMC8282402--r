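# Flat "[section] / key: value" config files, shared by the regime definitions
# and the command-line interface. Values are parsed as numeric vectors
# (comma-separated) when possible, otherwise kept as strings.

parse_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list(); section <- ".global"
  for (ln in lines) {
    sec <- regmatches(ln, regexec("^\\s*\\[([^]]+)\\]\\s*$", ln))[[1]]
    if (length(sec) == 2) { section <- sec[2]; next }
    kv <- regmatches(ln, regexec("^\\s*([^:=]+)\\s*[:=]\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3) abort(sprintf("Malformed config line: %s", ln))
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) > 0 && !anyNA(num)) val <- num
    if (is.null(out[[section]])) out[[section]] <- list()
    out[[section]][[key]] <- val
  }
  out
}

default_regime_config <- function() {
  system.file("extdata", "regimes.conf", package = "ecgarch", mustWork = TRUE)
}
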