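# Individualized filter bank: three Butterworth sub-bands covering the
# alpha+beta+gamma (8-60 Hz), beta+gamma (12-60 Hz) and gamma (30-60 Hz)
# ranges. Per-band classification scores are recombined with weights
# a_j = rho^(j) / sum(rho), where rho^(j) is the maximal canonical
# correlation obtained on the training data after filtering with band j --
# so bands dominated by non-stimulus activity (e.g. strong alpha) are
# down-weighted for that individual.

#' Design a Butterworth filter bank
#'
#' @param bands List of `c(low, high)` cut-off pairs in Hz. Defaults to the
#'   three sub-bands 8-60, 12-60 and 30-60 Hz.
#' @param order Band-pass filter order (default 8; must be even, realized
#'   as a Butterworth prototype of order `order / 2`).
#' @param sampling_rate Sampling rate in Hz.
#' @return A `cvep_filterbank` with one stable band-pass filter per band and
#'   empty weights (filled during decoder training).
#' @export
design_filter_bank <- function(bands = list(c(8, 60), c(12, 60), c(30, 60)),
                               order = 8, sampling_rate = 600) {
  check_positive(sampling_rate, "sampling_rate")
  if (order < 2 || order %% 2 != 0) stop("`order` must be a positive even integer")
  if (!is.list(bands) || length(bands) < 1) stop("`bands` must be a non-empty list")
  nyq <- sampling_rate / 2
  filters <- lapply(bands, function(b) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] >= nyq)
      stop("invalid band: need 0 < low < high < sampling_rate / 2")
    flt <- signal::butter(order / 2, c(b[1], b[2]) / nyq, type = "pass")
    # stability: all poles strictly inside the unit circle
    poles <- polyroot(rev(flt$a))
    if (any(Mod(poles) >= 1))
      stop("unstable filter design for band ", b[1], "-", b[2], " Hz")
    flt
  })
  structure(
    list(bands = bands, order = order, sampling_rate = sampling_rate,
         filters = filters, weights = NULL, rhos = NULL),
    class = "cvep_filterbank")
}

#' @export
print.cvep_filterbank <- function(x, ...) {
  bb <- vapply(x$bands, function(b) paste0(b[1], "-", b[2]), character(1))
  cat("c-VEP filter bank @ ", x$sampling_rate, " Hz: order-", x$order,
      " Butterworth bands ", paste(bb, collapse = ", "), " Hz", sep = "")
  if (!is.null(x$weights))
    cat("; weights ", paste(signif(x$weights, 3), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Apply one sub-band filter to a multichannel signal
#'
#' Zero-phase (forward-backward) filtering by default so templates and
#' buffers keep their code-phase alignment; causal single-pass filtering is
#' available for strictly online processing.
#'
#' @param x `channels x samples` matrix (a plain vector is treated as one
#'   channel).
#' @param bank A `cvep_filterbank`.
#' @param j Band index.
#' @param causal If `TRUE`, use single-pass causal filtering.
#' @return Filtered matrix of the same shape.
#' @export
apply_subband <- function(x, bank, j, causal = FALSE) {
  stopifnot(inherits(bank, "cvep_filterbank"))
  if (j < 1 || j > length(bank$filters)) stop("band index out of range")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  flt <- bank$filters[[j]]
  warmup <- 3 * (length(flt$a) - 1)
  if (ncol(x) <= warmup)
    stop("signal too short for the filter warm-up (need > ", warmup,
         " samples)")
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- if (causal) signal::filter(flt, x[ch, ])
                 else signal::filtfilt(flt, x[ch, ])
  }
  out
}

#' Individualized sub-band weights
#'
#' Normalizes the per-band maximal canonical correlations to weights
#' `a_j = rho_j / sum(rho)`, which sum to one.
#'
#' @param rhos Non-negative per-band canonical correlations, not all zero.
#' @return Numeric weight vector summing to 1.
#' @export
compute_band_weights <- function(rhos) {
  if (!is.numeric(rhos) || length(rhos) < 1 || any(!is.finite(rhos)) ||
      any(rhos < 0))
    stop("`rhos` must be non-negative finite numbers")
  s <- sum(rhos)
  if (s <= 0) stop("degenerate weights: all per-band correlations are zero")
  rhos / s
}
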