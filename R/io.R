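# Containers and readers. Trial sets and online streams are stored in a
# self-describing plain-text format: a small key-value header followed by
# whitespace-delimited sample values. The default payload encoding is C99
# hexadecimal floating point ("%a"), which round-trips doubles
# bit-identically through text; a decimal encoding ("%.17g") is provided
# for inspection and interoperability. EDF recordings can be ingested
# read-only.

format_values <- function(x, encoding) {
  if (encoding == "hex") sprintf("%a", x) else sprintf("%.17g", x)
}

#' Write / read a trial set container
#'
#' Plain-text container: header lines (`sampling_rate`, `m`, `n`,
#' `n_trials`, `n_b`, `labels`), then one line of `n` values per channel,
#' trial-major. The `"hex"` encoding round-trips arrays bit-identically;
#' `"decimal"` is human-readable and exact to full double precision.
#'
#' @param trials A `cvep_trialset`.
#' @param path Output file path.
#' @param encoding `"hex"` (default) or `"decimal"`.
#' @return `read_trialset` returns a `cvep_trialset`.
#' @export
write_trialset <- function(trials, path, encoding = c("hex", "decimal")) {
  stopifnot(inherits(trials, "cvep_trialset"))
  encoding <- match.arg(encoding)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "cvep_trialset 1",
    paste("sampling_rate", format_values(trials$sampling_rate, "decimal")),
    paste("m", trials$m),
    paste("n", trials$n),
    paste("n_trials", length(trials$trials)),
    paste("n_b", trials$n_b),
    paste("labels", paste(trials$labels, collapse = " "))), con)
  for (z in trials$trials)
    writeLines(apply(z, 1, function(r)
      paste(format_values(r, encoding), collapse = " ")), con)
  invisible(path)
}

read_header <- function(lines, magic) {
  if (length(lines) == 0 || !startsWith(lines[1], magic))
    stop("format error: not a ", magic, " file")
  hdr <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ")[[1]]
    hdr[[parts[1]]] <- parts[-1]
  }
  hdr
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- read_header(readLines(con, n = 7), "cvep_trialset")
  for (f in c("sampling_rate", "m", "n", "n_trials", "labels"))
    if (is.null(hdr[[f]])) stop("format error: missing header field `", f, "`")
  m <- as.integer(hdr$m); n <- as.integer(hdr$n)
  n_trials <- as.integer(hdr$n_trials)
  labels <- as.integer(hdr$labels)
  if (length(labels) != n_trials)
    stop("format error: `labels` length does not match `n_trials`")
  vals <- as.numeric(scan(con, what = character(), quiet = TRUE))
  if (length(vals) != n_trials * m * n)
    stop("format error: expected ", n_trials * m * n, " values, found ",
         length(vals))
  trials <- lapply(seq_len(n_trials), function(i) {
    block <- vals[((i - 1) * m * n + 1):(i * m * n)]
    matrix(block, m, n, byrow = TRUE)
  })
  new_trialset(trials, labels, as.numeric(hdr$sampling_rate),
               n_b = as.integer(hdr$n_b %||% NA_integer_))
}

#' Write / read an online-stream container
#'
#' Same plain-text scheme as the trial set container, with the intent log
#' (onset sample, target, segment and pause lengths) stored in the header.
#'
#' @param stream A `cvep_stream`.
#' @param path File path.
#' @param encoding `"hex"` (default) or `"decimal"`.
#' @return `read_stream` returns a `cvep_stream`.
#' @export
write_stream <- function(stream, path, encoding = c("hex", "decimal")) {
  stopifnot(inherits(stream, "cvep_stream"))
  encoding <- match.arg(encoding)
  il <- stream$intent_log
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "cvep_stream 1",
    paste("sampling_rate", format_values(stream$sampling_rate, "decimal")),
    paste("m", nrow(stream$samples)),
    paste("T", ncol(stream$samples)),
    paste("onset", paste(il$onset, collapse = " ")),
    paste("target", paste(il$target, collapse = " ")),
    paste("n_samples", paste(il$n_samples, collapse = " ")),
    paste("pause_samples", paste(il$pause_samples, collapse = " "))), con)
  writeLines(apply(stream$samples, 1, function(r)
    paste(format_values(r, encoding), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- read_header(readLines(con, n = 8), "cvep_stream")
  for (f in c("sampling_rate", "m", "T", "onset", "target"))
    if (is.null(hdr[[f]])) stop("format error: missing header field `", f, "`")
  m <- as.integer(hdr$m); Tn <- as.integer(hdr$T)
  vals <- as.numeric(scan(con, what = character(), quiet = TRUE))
  if (length(vals) != m * Tn)
    stop("format error: expected ", m * Tn, " values, found ", length(vals))
  structure(
    list(samples = matrix(vals, m, Tn, byrow = TRUE),
         intent_log = data.frame(
           onset = as.integer(hdr$onset),
           target = as.integer(hdr$target),
           n_samples = as.integer(hdr$n_samples),
           pause_samples = as.integer(hdr$pause_samples)),
         sampling_rate = as.numeric(hdr$sampling_rate)),
    class = "cvep_stream")
}

trim_ascii <- function(x) sub(" +$", "", sub("^ +", "", x))

read_edf_field <- function(con, width, n = 1) {
  trim_ascii(vapply(seq_len(n), function(i)
    rawToChar(readBin(con, "raw", width)), character(1)))
}

#' Read an EDF recording
#'
#' Minimal European Data Format reader: parses the fixed-layout ASCII
#' header, decodes the 16-bit samples of the requested channels and scales
#' them to physical units. All requested channels must share one sampling
#' rate; mixed-rate selections raise an error directing the user to
#' resample externally.
#'
#' @param path Path to an EDF file.
#' @param channels Channel labels to extract (default: all).
#' @return List with `data` (`channels x samples` matrix, physical units),
#'   `sampling_rate`, and `channels`.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 8)                         # version
  read_edf_field(con, 80); read_edf_field(con, 80)
  read_edf_field(con, 8); read_edf_field(con, 8)
  header_bytes <- as.integer(read_edf_field(con, 8))
  read_edf_field(con, 44)
  n_records <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  labels <- read_edf_field(con, 16, ns)
  read_edf_field(con, 80, ns); read_edf_field(con, 8, ns)
  phys_min <- as.numeric(read_edf_field(con, 8, ns))
  phys_max <- as.numeric(read_edf_field(con, 8, ns))
  dig_min <- as.numeric(read_edf_field(con, 8, ns))
  dig_max <- as.numeric(read_edf_field(con, 8, ns))
  read_edf_field(con, 80, ns)
  spr <- as.integer(read_edf_field(con, 8, ns))
  read_edf_field(con, 32, ns)
  seek(con, header_bytes)

  channels <- channels %||% labels
  sel <- match(channels, labels)
  if (anyNA(sel))
    stop("channel(s) not found in EDF file: ",
         paste(channels[is.na(sel)], collapse = ", "))
  if (length(unique(spr[sel])) != 1)
    stop("selected channels have different sampling rates; ",
         "resample the recording before import")
  rate <- spr[sel[1]] / rec_dur

  data <- matrix(0, length(sel), n_records * spr[sel[1]])
  for (r in seq_len(n_records)) {
    for (si in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[si], size = 2, endian = "little")
      pos <- match(si, sel)
      if (!is.na(pos)) {
        g <- (phys_max[si] - phys_min[si]) / (dig_max[si] - dig_min[si])
        cols <- ((r - 1) * spr[si] + 1):(r * spr[si])
        data[pos, cols] <- (raw - dig_min[si]) * g + phys_min[si]
      }
    }
  }
  list(data = data, sampling_rate = rate, channels = channels)
}

# Minimal EDF writer used to build synthetic fixtures at run/test time
# (not exported; real recordings are ingested, never written).
write_edf <- function(data, sampling_rate, path, labels = NULL) {
  stopifnot(is.matrix(data), sampling_rate == round(sampling_rate))
  m <- nrow(data); n <- ncol(data)
  labels <- labels %||% paste0("CH", seq_len(m))
  spr <- as.integer(sampling_rate)
  n_records <- as.integer(ceiling(n / spr))
  if (n < n_records * spr)
    data <- cbind(data, matrix(0, m, n_records * spr - n))
  # symmetric integer physical range per channel: short header fields and
  # a simple, exactly representable scale
  amp <- pmax(ceiling(apply(abs(data), 1, max)), 1)
  phys_min <- -amp; phys_max <- amp
  dig_min <- -32768; dig_max <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("synthetic", 80), pad("synthetic cvepr fixture", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 + 256 * m, 8), pad("", 44), pad(n_records, 8), pad("1", 8),
    pad(m, 4),
    paste(pad(labels, 16), collapse = ""),
    paste(pad(rep("", m), 80), collapse = ""),
    paste(pad(rep("uV", m), 8), collapse = ""),
    paste(pad(phys_min, 8), collapse = ""),
    paste(pad(phys_max, 8), collapse = ""),
    paste(pad(rep(dig_min, m), 8), collapse = ""),
    paste(pad(rep(dig_max, m), 8), collapse = ""),
    paste(pad(rep("", m), 80), collapse = ""),
    paste(pad(rep(spr, m), 8), collapse = ""),
    paste(pad(rep("", m), 32), collapse = "")), con, eos = NULL)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(m)) {
      cols <- ((r - 1) * spr + 1):(r * spr)
      g <- (phys_max[ch] - phys_min[ch]) / (dig_max - dig_min)
      dig <- round((data[ch, cols] - phys_min[ch]) / g + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Default run configuration
#'
#' The 32-target protocol: 32 channels at 600 Hz, 63-bit code at 60 Hz,
#' shift step 2 bits, 2-cycle (2.1 s) trials, 4 training blocks,
#' threshold 0.1.
#'
#' @return Named list of simulation / protocol / model parameters, the
#'   schema accepted by the `simulate` CLI subcommand's YAML config.
#' @export
default_run_config <- function() {
  list(seed = 1, m = 32, sampling_rate = 600, snr = 1, alpha_amp = 0.5,
       K = 32, shift_step = 2, update_rate = 60, cycles = 2, n_b = 4,
       s = 4, beta = 0.1, bands = list(c(8, 60), c(12, 60), c(30, 60)),
       order = 8)
}
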