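# Circular-shift m-sequence codebooks.
#
# Stimulation uses a 63-bit maximal-length sequence (m-sequence) updated at
# 60 Hz; each speller target flickers with a circularly shifted copy of the
# same base sequence, so targets are distinguished purely by code phase.

#' The bundled 63-bit m-sequence
#'
#' Base binary code driving the first (unshifted) stimulus. An m-sequence of
#' length 63 is balanced up to one bit: this one contains 32 ones and 31
#' zeros, and its circular autocorrelation is two-valued, which is what makes
#' phase-shifted copies nearly orthogonal references for decoding.
#'
#' @format A length-one character string of 63 `'0'`/`'1'` characters.
#' @export
cvep_mseq63 <- "101011001101110110100100111000101111001010001100001000001111110"

check_bitstring <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("code must be a single non-empty character string")
  if (grepl("[^01]", seq))
    stop("invalid alphabet: code may contain only '0' and '1'")
  invisible(seq)
}

#' Circularly rotate a bit string to the left
#'
#' @param seq Bit string (characters `'0'`/`'1'`).
#' @param bits Non-negative number of positions to rotate; rotation is taken
#'   modulo the string length, so a full-cycle rotation is the identity.
#' @return The rotated bit string, same length.
#' @examples
#' rotate_left("101000", 2)  # "100010"
#' @export
rotate_left <- function(seq, bits) {
  check_bitstring(seq)
  if (!is.numeric(bits) || length(bits) != 1L || is.na(bits) || bits < 0)
    stop("`bits` must be a single non-negative number")
  L <- nchar(seq)
  k <- as.integer(bits %% L)
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, L), substr(seq, 1L, k))
}

#' Build a circular-shift codebook
#'
#' Target `k` (1-based) flickers with the base sequence rotated left by
#' `(k - 1) * shift_step` bits, so target 1 uses the unshifted base. The
#' default protocol uses a step of 2 bits for the 32-target speller and
#' 4 bits for the 4-target speller.
#'
#' @param base Base bit string (default: the bundled 63-bit m-sequence).
#' @param K Number of targets.
#' @param shift_step Bits of circular left shift between consecutive targets.
#' @param update_rate Stimulus update rate in Hz (default 60).
#' @return A `cvep_codebook` object with fields `base`, `K`, `shift_step`,
#'   `update_rate`, `shifts` (bit shifts, starting at 0) and `codes`.
#' @examples
#' cb <- build_codebook(K = 32, shift_step = 2)
#' cb$shifts[1:4]
#' @export
build_codebook <- function(base = cvep_mseq63, K, shift_step,
                           update_rate = 60) {
  check_bitstring(base)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("`K` must be a positive integer")
  if (!is.numeric(shift_step) || length(shift_step) != 1L ||
      shift_step < 0 || shift_step != round(shift_step))
    stop("`shift_step` must be a non-negative integer")
  check_positive(update_rate, "update_rate")
  K <- as.integer(K)
  shifts <- (seq_len(K) - 1L) * as.integer(shift_step)
  codes <- vapply(shifts, function(s) rotate_left(base, s), character(1))
  if (anyDuplicated(codes))
    stop("shift collision: two targets received identical codes; ",
         "require shift_step * (K - 1) < code length")
  structure(
    list(base = base, K = K, shift_step = as.integer(shift_step),
         update_rate = update_rate, shifts = shifts, codes = codes),
    class = "cvep_codebook")
}

#' @export
print.cvep_codebook <- function(x, ...) {
  cat("c-VEP codebook: ", x$K, " targets, ", nchar(x$base),
      "-bit base code, shift step ", x$shift_step, " bits, update ",
      x$update_rate, " Hz (cycle ", format(code_cycle_duration(x)),
      " s)\n", sep = "")
  invisible(x)
}

#' Duration of one full stimulation cycle
#'
#' @param codebook A `cvep_codebook`.
#' @return Cycle duration in seconds, `L / update_rate` (1.05 s for the
#'   63-bit code at 60 Hz).
#' @export
code_cycle_duration <- function(codebook) {
  stopifnot(inherits(codebook, "cvep_codebook"))
  check_positive(codebook$update_rate, "update_rate")
  nchar(codebook$base) / codebook$update_rate
}

#' Expand a code to the EEG sampling grid
#'
#' Replicates each bit `sampling_rate / update_rate` times, mapping bit
#' shifts to sample shifts (10 samples per bit at 600 Hz / 60 Hz).
#'
#' @param code Bit string.
#' @param sampling_rate EEG sampling rate in Hz; must be an integer multiple
#'   of `update_rate`.
#' @param update_rate Stimulus update rate in Hz.
#' @return Integer vector of 0/1 of length `L * sampling_rate / update_rate`.
#' @export
upsample_code <- function(code, sampling_rate, update_rate) {
  check_bitstring(code)
  check_positive(sampling_rate, "sampling_rate")
  check_positive(update_rate, "update_rate")
  if (sampling_rate %% update_rate != 0)
    stop("sampling_rate must be divisible by update_rate")
  f <- as.integer(sampling_rate %/% update_rate)
  bits <- as.integer(strsplit(code, "")[[1]])
  rep(bits, each = f)
}

samples_per_bit <- function(sampling_rate, update_rate) {
  if (sampling_rate %% update_rate != 0)
    stop("sampling_rate must be divisible by update_rate")
  as.integer(sampling_rate %/% update_rate)
}

#' Serialize or restore a codebook as JSON
#'
#' The JSON document stores `base`, `K`, `shift_step` and `update_rate`;
#' codes and shifts are reconstructed on read.
#'
#' @param codebook A `cvep_codebook`.
#' @param path File path.
#' @return `read_codebook` returns a `cvep_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "cvep_codebook"))
  jsonlite::write_json(
    list(base = codebook$base, K = codebook$K,
         shift_step = codebook$shift_step,
         update_rate = codebook$update_rate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("base", "K", "shift_step", "update_rate"))
    if (is.null(doc[[f]])) stop("codebook file missing field `", f, "`")
  build_codebook(doc$base, doc$K, doc$shift_step, doc$update_rate)
}
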