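# Target identification. EEG arrives in 0.05 s blocks (n_a = 30 samples at
# 600 Hz) that accumulate in a buffer Y. Once the buffer holds at least
# 0.25 s (150 samples), correlation scores lambda_k between the buffer and
# the first n_y columns of each class template are computed per sub-band,
# combined with the individualized band weights, and the candidate
# C = argmax_k lambda_k is emitted only when the margin between the best
# and second-best score strictly exceeds the threshold beta (asynchronous
# mode; beta = 0 reproduces the synchronous variant). While no decision is
# reached the window extends; when the buffer is full (n = 1260 samples)
# the oldest n/2 = 630 columns are shuffled out. After an emitted decision
# the buffer is cleared and a 1 s gaze-shift pause follows.

min_window_samples <- function(model) as.integer(round(0.25 * model$sampling_rate))
block_samples <- function(model) as.integer(round(0.05 * model$sampling_rate))

# Score between two stacked s x n_y projected signals.
stacked_score <- function(P, R, method) {
  if (method == "pearson") {
    a <- as.vector(P); b <- as.vector(R)
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("degenerate input: zero-variance projection")
    abs(stats::cor(a, b))
  } else {
    rho1(P, R)
  }
}

#' Correlation scores between a buffer and all class references
#'
#' For each sub-band the buffer is filtered, projected through the `s`
#' spatial filters, and compared with the (precomputed) projection of the
#' first `n_y` columns of each class template; the per-band scores are
#' combined with the individualized band weights.
#'
#' @param buffer `m x n_y` matrix with `n_y >= 0.25 * sampling_rate`.
#' @param model A `cvep_decoder_model`.
#' @return Numeric vector of `K` combined scores `lambda_k`.
#' @export
correlation_scores <- function(buffer, model) {
  stopifnot(inherits(model, "cvep_decoder_model"))
  if (is.vector(buffer)) buffer <- matrix(buffer, nrow = 1)
  if (nrow(buffer) != model$m)
    stop("buffer has ", nrow(buffer), " channels; model expects ", model$m)
  n_y <- ncol(buffer)
  if (n_y < min_window_samples(model))
    stop("buffer too short: ", n_y, " < ", min_window_samples(model),
         " samples (0.25 s)")
  if (n_y > model$n)
    stop("buffer longer than the templates (", model$n, " samples)")
  if (all(buffer == 0)) stop("degenerate input: all-zero buffer")
  K <- model$codebook$K
  lambda <- numeric(K)
  for (j in seq_along(model$bands)) {
    bm <- model$bands[[j]]
    bf <- if (is.null(model$bank)) buffer
          else apply_subband(buffer, model$bank, j)
    P <- crossprod(bm$W, bf)
    for (k in seq_len(K)) {
      R <- bm$proj_templates[[k]][, seq_len(n_y), drop = FALSE]
      lambda[k] <- lambda[k] +
        model$weights[j] * stacked_score(P, R, model$score_method)
    }
  }
  lambda
}

new_decision <- function(lambda, n_y, sampling_rate, time = NA_real_) {
  ord <- order(lambda, decreasing = TRUE)
  structure(
    list(class = ord[1], scores = lambda,
         margin = if (length(lambda) > 1) lambda[ord[1]] - lambda[ord[2]]
                  else lambda[1],
         window_used = n_y / sampling_rate,
         time_of_decision = time),
    class = "cvep_decision")
}

#' @export
print.cvep_decision <- function(x, ...) {
  cat("decision: class ", x$class, " (margin ", signif(x$margin, 4),
      ", window ", x$window_used, " s)\n", sep = "")
  invisible(x)
}

#' Synchronous classification of a buffer
#'
#' Computes the combined scores and returns the argmax candidate without
#' applying any threshold (the synchronous variant, `beta = 0`). Ties go to
#' the lowest class index.
#'
#' @inheritParams correlation_scores
#' @return A `cvep_decision` with fields `class`, `scores`, `margin`,
#'   `window_used`.
#' @export
classify_window <- function(buffer, model) {
  lambda <- correlation_scores(buffer, model)
  new_decision(lambda, ncol(buffer), model$sampling_rate)
}

#' Create an asynchronous decoder state
#'
#' @param model A `cvep_decoder_model`.
#' @param beta Decision threshold (defaults to the model's stored value).
#' @param n_a Samples per incoming block; must divide `n / 2`. Defaults to
#'   `0.05 * sampling_rate` (30 samples at 600 Hz).
#' @return A `cvep_decoder_state` with an empty buffer.
#' @export
new_decoder_state <- function(model, beta = model$beta,
                              n_a = block_samples(model)) {
  stopifnot(inherits(model, "cvep_decoder_model"))
  if ((model$n / 2) %% n_a != 0)
    stop("block size n_a = ", n_a, " must divide n/2 = ", model$n / 2)
  structure(
    list(model = model, beta = beta, n_a = as.integer(n_a),
         min_window = min_window_samples(model),
         buffer = matrix(numeric(0), model$m, 0), n_y = 0L,
         blocks_seen = 0L),
    class = "cvep_decoder_state")
}

#' Push one EEG block into the asynchronous decoder
#'
#' Appends the block (shuffling out the oldest `n/2` columns first when the
#' buffer is full), computes scores once the window reaches 0.25 s, and
#' emits a decision only when the score margin strictly exceeds `beta`.
#' After an emitted decision the buffer is cleared.
#'
#' @param state A `cvep_decoder_state`.
#' @param block `m x n_a` matrix of new samples.
#' @return List with the updated `state` and `decision` (a `cvep_decision`
#'   or `NULL`).
#' @export
push_block <- function(state, block) {
  stopifnot(inherits(state, "cvep_decoder_state"))
  if (is.vector(block)) block <- matrix(block, nrow = state$model$m)
  if (nrow(block) != state$model$m || ncol(block) != state$n_a)
    stop("block must be ", state$model$m, " x ", state$n_a)
  n <- state$model$n
  if (state$n_y == n) {
    keep <- (n / 2 + 1):n
    state$buffer <- state$buffer[, keep, drop = FALSE]
    state$n_y <- as.integer(n / 2)
  }
  state$buffer <- cbind(state$buffer, block)
  state$n_y <- state$n_y + state$n_a
  state$blocks_seen <- state$blocks_seen + 1L
  decision <- NULL
  if (state$n_y >= state$min_window) {
    lambda <- correlation_scores(state$buffer, state$model)
    cand <- new_decision(lambda, state$n_y, state$model$sampling_rate)
    if (cand$margin > state$beta) {
      decision <- cand
      state$buffer <- matrix(numeric(0), state$model$m, 0)
      state$n_y <- 0L
    }
  }
  list(state = state, decision = decision)
}

#' Decode an online stream into a sequence of selections
#'
#' Feeds the stream to the asynchronous decoder in 0.05 s blocks. For each
#' intended target the decoder starts with an empty buffer at the segment
#' onset; when a decision is emitted the remaining flicker segment and the
#' 1 s gaze-shift pause are skipped (data collection pauses). A segment
#' that produces no decision within `max_dwell` seconds (or by its end) is
#' logged as a timeout -- the non-control state.
#'
#' @param stream A `cvep_stream` from [simulate_online_stream()].
#' @param model A `cvep_decoder_model`.
#' @param beta Decision threshold (defaults to the model's stored value).
#' @param gaze_shift Gaze-shift pause added to every selection time, in
#'   seconds (default 1).
#' @param max_dwell Maximum seconds of flicker per intent before giving up.
#' @return A `cvep_session` data frame with one row per intent: `target`,
#'   `decided`, `class`, `correct`, `window_used`, `selection_time`,
#'   `margin`.
#' @export
run_session <- function(stream, model, beta = model$beta, gaze_shift = 1,
                        max_dwell = 10) {
  stopifnot(inherits(stream, "cvep_stream"),
            inherits(model, "cvep_decoder_model"))
  if (stream$sampling_rate != model$sampling_rate)
    stop("stream and model sampling rates differ")
  n_a <- block_samples(model)
  out <- vector("list", nrow(stream$intent_log))
  for (i in seq_len(nrow(stream$intent_log))) {
    onset <- stream$intent_log$onset[i]
    seg_len <- stream$intent_log$n_samples[i]
    max_blocks <- min(seg_len %/% n_a,
                      floor(max_dwell * model$sampling_rate / n_a))
    state <- new_decoder_state(model, beta = beta, n_a = n_a)
    decision <- NULL
    for (b in seq_len(max_blocks)) {
      cols <- (onset + (b - 1L) * n_a):(onset + b * n_a - 1L)
      res <- push_block(state, stream$samples[, cols, drop = FALSE])
      state <- res$state
      if (!is.null(res$decision)) { decision <- res$decision; break }
    }
    out[[i]] <- if (is.null(decision)) {
      data.frame(target = stream$intent_log$target[i], decided = FALSE,
                 class = NA_integer_, correct = NA,
                 window_used = NA_real_, selection_time = NA_real_,
                 margin = NA_real_)
    } else {
      data.frame(target = stream$intent_log$target[i], decided = TRUE,
                 class = decision$class,
                 correct = decision$class == stream$intent_log$target[i],
                 window_used = decision$window_used,
                 selection_time = decision$window_used + gaze_shift,
                 margin = decision$margin)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cvep_session", class(res))
  res
}
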