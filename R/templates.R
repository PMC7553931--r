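# Phase alignment of training trials and construction of per-class
# templates. All trials are circularly shifted to bit-shift 0 (the phase of
# target 1), averaged into the grand average, and per-class templates are
# circular column-shifts of that average by each target's bit shift times
# the samples-per-bit factor. Shifts are applied within each stimulation
# cycle so cycle boundaries stay aligned in multi-cycle trials.

#' Align training trials to bit-shift 0
#'
#' A trial recorded while the user fixated target `k` (whose code is the
#' base rotated left by `shifts[k]` bits) is rotated right by
#' `shifts[k] * samples_per_bit` samples within each cycle, so that all
#' aligned trials share the phase of target 1.
#'
#' @param trials A `cvep_trialset`.
#' @param codebook A `cvep_codebook`.
#' @return List of aligned `m x n` matrices (same order as the input trials).
#' @export
align_trials <- function(trials, codebook) {
  stopifnot(inherits(trials, "cvep_trialset"),
            inherits(codebook, "cvep_codebook"))
  spb <- samples_per_bit(trials$sampling_rate, codebook$update_rate)
  cycle_len <- nchar(codebook$base) * spb
  if (trials$n %% cycle_len != 0)
    stop("trial length ", trials$n,
         " is not a whole number of stimulation cycles (", cycle_len,
         " samples)")
  if (any(trials$labels < 1 | trials$labels > codebook$K))
    stop("trial labels out of range 1..K")
  lapply(seq_along(trials$trials), function(i) {
    sh <- codebook$shifts[trials$labels[i]] * spb
    col_rotate_within_cycles(trials$trials[[i]], -sh, cycle_len)
  })
}

#' Grand-average of aligned trials
#'
#' @param aligned Non-empty list of equally shaped `m x n` matrices.
#' @return Element-wise mean matrix.
#' @export
grand_average <- function(aligned) {
  if (!is.list(aligned) || length(aligned) == 0)
    stop("`aligned` must be a non-empty list of matrices")
  Reduce(`+`, aligned) / length(aligned)
}

#' Build per-class templates from the grand average
#'
#' Template `X_k` is the grand average rotated left (within each cycle) by
#' `shifts[k] * samples_per_bit` samples, mirroring how each target's code
#' is a left-rotated copy of the base code. `X_1` equals the grand average.
#'
#' @param zbar Grand-average `m x n` matrix.
#' @param codebook A `cvep_codebook`.
#' @param samples_per_bit Samples per code bit (10 at 600 Hz / 60 Hz).
#' @return A `cvep_templates` object with fields `grand_average`,
#'   `class_templates` (list of K matrices), `samples_per_bit`, `codebook`.
#' @export
make_class_templates <- function(zbar, codebook, samples_per_bit) {
  stopifnot(is.matrix(zbar), inherits(codebook, "cvep_codebook"))
  cycle_len <- nchar(codebook$base) * samples_per_bit
  if (ncol(zbar) %% cycle_len != 0)
    stop("template length not divisible by the cycle length in samples")
  tmpl <- lapply(codebook$shifts, function(sh)
    col_rotate_within_cycles(zbar, sh * samples_per_bit, cycle_len))
  structure(
    list(grand_average = zbar, class_templates = tmpl,
         samples_per_bit = samples_per_bit, codebook = codebook),
    class = "cvep_templates")
}
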