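# Performance metrics -- classification accuracy, Wolpaw information
# transfer rate (ITR) and output characters per minute (OCM) -- plus the
# offline 4-fold stratified cross-validation harness used for the window
# sweep, channel-subset and standard-vs-filter-bank comparisons.

#' Classification accuracy of a selection log
#'
#' @param x Logical vector of per-selection correctness, or anything with a
#'   `correct` column / `log` component (session data frames and spelling
#'   logs).
#' @return Fraction of correct selections in `[0, 1]`.
#' @export
selection_accuracy <- function(x) {
  if (inherits(x, "cvep_spelling_log")) x <- x$log
  if (is.data.frame(x)) x <- x$correct
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty selection log")
  mean(as.logical(x))
}

#' Information transfer rate (Wolpaw), bit/min
#'
#' `B_m = [log2 K + p log2 p + (1 - p) log2((1 - p) / (K - 1))] / (t / 60)`
#' with the convention `0 * log2(0) = 0`. Accuracies below chance (`1/K`)
#' are reported as 0 bit/min with a warning.
#'
#' @param p Accuracy fraction in `[0, 1]`.
#' @param K Number of classes (>= 2).
#' @param t Mean selection time in seconds (> 0), including the gaze-shift
#'   pause.
#' @param warn Warn when clamping a below-chance accuracy.
#' @return ITR in bit/min.
#' @examples
#' itr(1, 4, 2)        # 60: two bits every two seconds
#' itr(0.5, 2, 3)      # 0: chance level
#' @export
itr <- function(p, K, t, warn = TRUE) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must be in [0, 1]")
  if (!is.numeric(K) || K < 2) stop("`K` must be >= 2")
  check_positive(t, "t")
  if (p < 1 / K - 1e-15) {
    # the bracket is a KL divergence and turns positive again far below
    # chance; a below-chance "information rate" is meaningless, report 0
    if (warn) warning("accuracy below chance level 1/K; ITR clamped to 0")
    return(0)
  }
  xlog2 <- function(x) if (x <= 0) 0 else x * log2(x)
  bits <- log2(K) + xlog2(p) +
    if (p >= 1) 0 else (1 - p) * log2((1 - p) / (K - 1))
  if (abs(bits) < 1e-12) bits <- 0         # p = 1/K up to rounding
  bits / (t / 60)
}

#' Output characters per minute
#'
#' Number of characters in the final (fully corrected) output divided by
#' the total spelling time in minutes.
#'
#' @param n_chars Characters in the final correct text.
#' @param total_time_min Total spelling time in minutes (> 0).
#' @return Characters per minute.
#' @export
ocm <- function(n_chars, total_time_min) {
  if (!is.numeric(n_chars) || n_chars < 0) stop("`n_chars` must be >= 0")
  check_positive(total_time_min, "total_time_min")
  n_chars / total_time_min
}

#' Summarize a decoded or simulated session
#'
#' @param x A `cvep_session` (from [run_session()]) or `cvep_spelling_log`
#'   (from the copy-spelling simulators; needs per-selection times either
#'   logged or supplied via `selection_time`).
#' @param K Number of classes used for the ITR (for the 4-target speller
#'   this is the number of targets per step, i.e. 4).
#' @param n_chars Characters in the final correct output; defaults to what
#'   the log reports.
#' @param selection_time Mean selection time in seconds, if not logged.
#' @return A `cvep_session_metrics` list: `p`, `t`, `B_m`, `ocm`, `K`,
#'   `n_selections`, `n_chars`.
#' @export
session_metrics <- function(x, K, n_chars = NULL, selection_time = NULL) {
  if (inherits(x, "cvep_session")) {
    times <- x$selection_time[x$decided]
    log <- x
    n_sel <- sum(x$decided)
  } else if (inherits(x, "cvep_spelling_log")) {
    times <- if ("selection_time" %in% names(x$log))
      x$log$selection_time[!is.na(x$log$selection_time)] else numeric(0)
    n_chars <- n_chars %||% x$n_chars
    log <- x$log
    n_sel <- x$n_selections
  } else stop("unsupported session object")
  t_mean <- if (length(times)) mean(times) else selection_time
  if (is.null(t_mean)) stop("no selection times available; pass `selection_time`")
  p <- selection_accuracy(log)
  n_chars <- n_chars %||% NA_integer_
  total_min <- n_sel * t_mean / 60
  structure(
    list(p = p, t = t_mean, B_m = itr(p, K, t_mean, warn = FALSE),
         ocm = if (is.na(n_chars)) NA_real_ else ocm(n_chars, total_min),
         K = K, n_selections = n_sel, n_chars = n_chars),
    class = "cvep_session_metrics")
}

#' @export
print.cvep_session_metrics <- function(x, ...) {
  cat("session: p = ", signif(x$p, 4), ", t = ", signif(x$t, 4),
      " s, ITR = ", signif(x$B_m, 4), " bit/min",
      if (!is.na(x$ocm)) paste0(", OCM = ", signif(x$ocm, 4), " char/min"),
      "\n", sep = "")
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle and deal
# round-robin so every fold holds (as nearly as possible) the same number
# of trials of each class.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (k in unique(labels)) {
      idx <- sample(which(labels == k))
      if (length(idx) < folds)
        stop("class ", k, " has fewer trials (", length(idx),
             ") than folds (", folds, ")")
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Offline cross-validated window sweep
#'
#' 4-fold stratified cross-validation of synchronous (`beta = 0`)
#' classification: per fold, a decoder model is trained on the training
#' split and every held-out trial is classified after truncation to each
#' requested window. Channel subsets (e.g. the 8 or 16 most occipital of 32
#' channels) restrict the montage before training, and `method` toggles the
#' individualized filter bank against the standard single-band pipeline.
#'
#' @param trials A labelled `cvep_trialset`.
#' @param codebook A `cvep_codebook`.
#' @param windows Classification windows in seconds (each >= 0.25 and at
#'   most the trial duration).
#' @param folds Number of folds (default 4).
#' @param channel_subset Optional integer vector of channel rows to keep.
#' @param method `"standard"` (no sub-band decomposition) or
#'   `"filterbank"`.
#' @param bank Filter bank for `method = "filterbank"`; defaults to the
#'   three-band design at the trial sampling rate.
#' @param s Number of spatial filters.
#' @param seed Seed for the stratified fold assignment.
#' @param gaze_shift Seconds added to each window for the ITR's selection
#'   time (default 1).
#' @return A `cvep_cv_report`: per-fold and mean accuracy and ITR per
#'   window.
#' @export
crossvalidate_offline <- function(trials, codebook, windows,
                                  folds = 4, channel_subset = NULL,
                                  method = c("standard", "filterbank"),
                                  bank = NULL, s = 4, seed = 1,
                                  gaze_shift = 1) {
  stopifnot(inherits(trials, "cvep_trialset"),
            inherits(codebook, "cvep_codebook"))
  method <- match.arg(method)
  fs <- trials$sampling_rate
  win_samples <- as.integer(round(windows * fs))
  if (any(win_samples > trials$n))
    stop("window exceeds the trial length (", trials$n / fs, " s)")
  if (!is.null(channel_subset)) {
    if (any(channel_subset < 1 | channel_subset > trials$m))
      stop("channel subset out of range")
    trials$trials <- lapply(trials$trials,
                            function(z) z[channel_subset, , drop = FALSE])
    trials$m <- length(channel_subset)
  }
  if (method == "filterbank" && is.null(bank))
    bank <- design_filter_bank(sampling_rate = fs)
  if (method == "standard") bank <- NULL

  fold_id <- stratified_folds(trials$labels, folds, seed)
  acc <- matrix(NA_real_, folds, length(windows))
  itr_mat <- matrix(NA_real_, folds, length(windows))
  for (f in seq_len(folds)) {
    tr_idx <- which(fold_id != f)
    te_idx <- which(fold_id == f)
    train <- new_trialset(trials$trials[tr_idx], trials$labels[tr_idx],
                          fs, n_b = trials$n_b)
    model <- train_decoder_model(train, codebook, bank = bank, s = s,
                                 beta = 0)
    for (wi in seq_along(windows)) {
      nw <- win_samples[wi]
      pred <- vapply(te_idx, function(i)
        classify_window(trials$trials[[i]][, seq_len(nw), drop = FALSE],
                        model)$class, integer(1))
      acc[f, wi] <- mean(pred == trials$labels[te_idx])
      itr_mat[f, wi] <- itr(acc[f, wi], codebook$K,
                            windows[wi] + gaze_shift, warn = FALSE)
    }
  }
  structure(
    list(folds = folds, windows = windows, accuracy = acc, itr = itr_mat,
         mean_accuracy = colMeans(acc), mean_itr = colMeans(itr_mat),
         method = method, channel_subset = channel_subset, seed = seed,
         K = codebook$K),
    class = "cvep_cv_report")
}

#' @export
print.cvep_cv_report <- function(x, ...) {
  cat("offline ", x$folds, "-fold CV (", x$method, ", K = ", x$K, ")\n",
      sep = "")
  df <- data.frame(window_s = x$windows,
                   mean_accuracy = signif(x$mean_accuracy, 4),
                   mean_itr = signif(x$mean_itr, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
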