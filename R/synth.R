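# Synthetic multichannel EEG with the statistical structure the decoder
# assumes: a code-locked evoked response mixed into the montage through a
# fixed topography, spatially correlated band-limited pink noise, and an
# optional amplitude-modulated alpha (8-12 Hz) contaminant on
# occipital-weighted channels.
#
# The evoked response is an impulse train at the onsets of '1' bits,
# circularly convolved (within each stimulation cycle) with a short damped
# oscillation. Because every target's code is a circular shift of the base
# code, noise-free responses of different targets are exact circular
# sample-shifts of one another -- the property the template/shifting logic
# of the decoder relies on.

#' Construct a synthetic forward model
#'
#' Defines everything deterministic about the simulated recording: channel
#' count, sampling rate, the evoked kernel (a damped oscillation of about
#' 100 ms), unit-norm topographies for the evoked source, the noise mixing
#' matrix, and the relative strength of noise and alpha contamination.
#'
#' The signal-to-noise ratio `snr` is defined as the ratio of evoked RMS to
#' noise RMS on the channel where the evoked topography is strongest;
#' `alpha_amp` is the RMS of the alpha contaminant relative to the pink
#' noise on its own strongest channel. `snr = Inf` yields noise-free data.
#'
#' @param m Number of channels (default 32).
#' @param sampling_rate Sampling rate in Hz (default 600).
#' @param snr Evoked-to-noise RMS ratio on the strongest channel.
#' @param alpha_amp Relative RMS amplitude of the 10 Hz contaminant
#'   (0 disables it).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   models and (with equal trial seeds) bit-identical data.
#' @param kernel_freq,kernel_tau,kernel_duration Damped-oscillation kernel:
#'   frequency (Hz), exponential decay constant (s), and length (s).
#' @return A `cvep_forward_model` object.
#' @export
make_forward_model <- function(m = 32, sampling_rate = 600, snr = 1,
                               alpha_amp = 0.5, seed = 1,
                               kernel_freq = 25, kernel_tau = 0.02,
                               kernel_duration = 0.1) {
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("`m` must be a positive integer")
  check_positive(sampling_rate, "sampling_rate")
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive")
  if (!is.numeric(alpha_amp) || alpha_amp < 0) stop("`alpha_amp` must be >= 0")
  m <- as.integer(m)

  tt <- seq(0, kernel_duration, by = 1 / sampling_rate)
  kernel <- exp(-tt / kernel_tau) * sin(2 * pi * kernel_freq * tt)
  kernel <- kernel / max(abs(kernel))

  with_seed(seed, {
    # Evoked topography: strongest over the last ("occipital") channels,
    # with a small seeded perturbation; unit norm.
    grad <- exp(-(m - seq_len(m)) / max(m / 4, 1))
    mixing <- grad + stats::rnorm(m, sd = 0.1 * max(grad))
    mixing[m] <- max(abs(mixing)) * 1.05   # keep the occipital lead dominant
    mixing <- mixing / sqrt(sum(mixing^2))

    noise_mixing <- matrix(stats::rnorm(m * m), m, m)
    noise_mixing <- sweep(noise_mixing, 2, sqrt(colSums(noise_mixing^2)), "/")
    # Mix in a common broad topography so noise is spatially correlated.
    noise_mixing <- 0.7 * noise_mixing + 0.3 * matrix(1 / sqrt(m), m, m)

    alpha_mixing <- exp(-(m - seq_len(m)) / max(m / 6, 1))
    alpha_mixing <- alpha_mixing / sqrt(sum(alpha_mixing^2))

    structure(
      list(m = m, sampling_rate = sampling_rate, snr = snr,
           alpha_amp = alpha_amp, seed = seed, kernel = kernel,
           mixing = mixing, noise_mixing = noise_mixing,
           alpha_mixing = alpha_mixing, noise_band = c(2, 100)),
      class = "cvep_forward_model")
  })
}

#' @export
print.cvep_forward_model <- function(x, ...) {
  cat("synthetic c-VEP forward model: ", x$m, " channels @ ",
      x$sampling_rate, " Hz, snr = ", x$snr, ", alpha_amp = ", x$alpha_amp,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Band-limited pink (1/f amplitude) noise of length n, unit variance.
pink_noise <- function(n, sampling_rate, band) {
  nh <- floor(n / 2)
  freqs <- seq(0, sampling_rate / 2, length.out = nh + 1)
  amp <- numeric(nh + 1)
  sel <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  amp[sel] <- 1 / sqrt(freqs[sel])
  phase <- stats::runif(nh + 1, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  half[1] <- 0
  spec <- if (n %% 2 == 0) {
    half[nh + 1] <- Re(half[nh + 1])  # Nyquist bin must be real
    c(half, Conj(rev(half[2:nh])))
  } else {
    c(half, Conj(rev(half[2:(nh + 1)])))
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Simulate noise-only EEG
#'
#' Spatially mixed band-limited pink noise plus the amplitude-modulated
#' 10 Hz alpha contaminant (if `alpha_amp > 0`). Used internally by the
#' trial and stream simulators and exposed for spectral checks and
#' non-control (noise-only) decoding experiments.
#'
#' @param model A `cvep_forward_model`.
#' @param n_samples Number of samples to generate.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return An `m x n_samples` matrix.
#' @export
simulate_noise <- function(model, n_samples, seed = NULL) {
  stopifnot(inherits(model, "cvep_forward_model"))
  with_seed(seed, {
    m <- model$m
    src <- vapply(seq_len(m),
                  function(i) pink_noise(n_samples, model$sampling_rate,
                                         model$noise_band),
                  numeric(n_samples))
    noise <- model$noise_mixing %*% t(src)
    if (model$alpha_amp > 0) {
      tt <- (seq_len(n_samples) - 1) / model$sampling_rate
      env <- 1 + 0.8 * sin(2 * pi * 0.4 * tt + stats::runif(1, 0, 2 * pi))
      wave <- env * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
      ch <- which.max(abs(model$alpha_mixing))
      alpha <- outer(model$alpha_mixing, wave)
      scale <- model$alpha_amp * rms(noise[ch, ]) /
        max(rms(alpha[ch, ]), .Machine$double.eps)
      noise <- noise + scale * alpha
    }
    noise
  })
}

# Deterministic noise-free evoked response for one target: impulse train at
# '1'-bit onsets, circularly convolved with the kernel within one cycle,
# tiled over cycles, mixed through the evoked topography.
evoked_response <- function(model, codebook, target, cycles) {
  stopifnot(inherits(model, "cvep_forward_model"),
            inherits(codebook, "cvep_codebook"))
  if (target < 1 || target > codebook$K || target != round(target))
    stop("`target` must be an index in 1..K")
  spb <- samples_per_bit(model$sampling_rate, codebook$update_rate)
  bits <- as.integer(strsplit(codebook$codes[[target]], "")[[1]])
  nc <- length(bits) * spb
  imp <- numeric(nc)
  imp[(which(bits == 1L) - 1L) * spb + 1L] <- 1
  kern <- numeric(nc)
  kl <- min(length(model$kernel), nc)
  kern[seq_len(kl)] <- model$kernel[seq_len(kl)]
  wave <- Re(stats::fft(stats::fft(imp) * stats::fft(kern), inverse = TRUE)) / nc
  outer(model$mixing, rep(wave, cycles))
}

#' Simulate one code-locked training trial
#'
#' @param model A `cvep_forward_model`.
#' @param codebook A `cvep_codebook`.
#' @param target Target index in `1..K`.
#' @param cycles Number of full stimulation cycles (default 2, i.e. a 2.1 s
#'   trial at the default protocol).
#' @param seed Optional seed for the noise draw; `NULL` uses the current
#'   RNG stream.
#' @return An `m x (cycles * L * sampling_rate / update_rate)` matrix.
#' @export
simulate_trial <- function(model, codebook, target, cycles = 2, seed = NULL) {
  if (cycles < 1 || cycles != round(cycles))
    stop("`cycles` must be a positive integer")
  evoked <- evoked_response(model, codebook, target, cycles)
  if (!is.finite(model$snr)) return(evoked)
  noise <- simulate_noise(model, ncol(evoked), seed = seed)
  ch <- which.max(abs(model$mixing))
  scale <- rms(evoked[ch, ]) /
    (model$snr * max(rms(noise[ch, ]), .Machine$double.eps))
  evoked + scale * noise
}

#' Simulate a full training set
#'
#' `n_b` blocks, each containing one trial per target (so `N = n_b * K`
#' trials), matching the training protocol: 4 blocks x 32 targets = 128
#' trials for the 32-target speller, 6 x 4 = 24 for the 4-target speller.
#'
#' @param model A `cvep_forward_model`.
#' @param codebook A `cvep_codebook`.
#' @param n_b Number of training blocks.
#' @param seed Seed for all noise draws in the set.
#' @param cycles Stimulation cycles per trial (default 2).
#' @return A `cvep_trialset`: list with `trials` (list of `m x n` matrices),
#'   `labels`, `sampling_rate`, `m`, `n`, `n_b`.
#' @export
simulate_training_set <- function(model, codebook, n_b, seed = 1, cycles = 2) {
  stopifnot(inherits(model, "cvep_forward_model"),
            inherits(codebook, "cvep_codebook"))
  if (n_b < 1 || n_b != round(n_b)) stop("`n_b` must be a positive integer")
  with_seed(seed, {
    trials <- list()
    labels <- integer(0)
    for (b in seq_len(n_b)) {
      for (k in seq_len(codebook$K)) {
        trials[[length(trials) + 1L]] <-
          simulate_trial(model, codebook, k, cycles = cycles, seed = NULL)
        labels <- c(labels, k)
      }
    }
    new_trialset(trials, labels, model$sampling_rate, n_b = n_b)
  })
}

new_trialset <- function(trials, labels, sampling_rate, n_b = NA_integer_) {
  stopifnot(length(trials) == length(labels), length(trials) >= 1)
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all trials must share the same channels x samples shape")
  structure(
    list(trials = trials, labels = as.integer(labels),
         sampling_rate = sampling_rate, m = dims[1, 1], n = dims[2, 1],
         n_b = n_b),
    class = "cvep_trialset")
}

#' @export
print.cvep_trialset <- function(x, ...) {
  cat("c-VEP trial set: ", length(x$trials), " trials of ", x$m, " x ", x$n,
      " @ ", x$sampling_rate, " Hz; ", length(unique(x$labels)),
      " classes\n", sep = "")
  invisible(x)
}

#' Simulate a continuous online stream
#'
#' Emits, for each intended target, a code-locked segment of up to
#' `max_duration` seconds (code phase 0 at segment onset) followed by a
#' flicker-free pause containing noise only. The intent log records segment
#' onsets so decoded selections can be scored.
#'
#' @param model A `cvep_forward_model`.
#' @param codebook A `cvep_codebook`.
#' @param intents Vector of intended target indices.
#' @param seed Seed for the noise draws.
#' @param max_duration Maximum flicker duration per intent in seconds.
#' @param pause Gaze-shift pause between intents in seconds (default 1).
#' @return A `cvep_stream`: list with `samples` (`m x T`), `intent_log`
#'   (data frame: `onset` sample, `target`, `n_samples`, `pause_samples`)
#'   and `sampling_rate`.
#' @export
simulate_online_stream <- function(model, codebook, intents, seed = 1,
                                   max_duration = 10, pause = 1) {
  stopifnot(inherits(model, "cvep_forward_model"),
            inherits(codebook, "cvep_codebook"))
  if (length(intents) < 1) stop("`intents` must be non-empty")
  if (any(intents < 1 | intents > codebook$K))
    stop("intent targets out of range 1..K")
  fs <- model$sampling_rate
  cyc <- code_cycle_duration(codebook)
  nc <- as.integer(round(cyc * fs))
  n_seg <- as.integer(ceiling(max_duration / cyc)) * nc
  n_pause <- as.integer(round(pause * fs))
  with_seed(seed, {
    chunks <- list()
    onset <- integer(0)
    pos <- 0L
    for (tg in intents) {
      evoked <- evoked_response(model, codebook, tg,
                                cycles = n_seg %/% nc)
      ch <- which.max(abs(model$mixing))
      scale <- 0
      seg <- if (is.finite(model$snr)) {
        noise <- simulate_noise(model, n_seg, seed = NULL)
        scale <- rms(evoked[ch, ]) /
          (model$snr * max(rms(noise[ch, ]), .Machine$double.eps))
        evoked + scale * noise
      } else evoked
      onset <- c(onset, pos + 1L)
      chunks[[length(chunks) + 1L]] <- seg
      pos <- pos + n_seg
      if (n_pause > 0) {
        # ongoing background EEG at the same amplitude, no flicker
        pz <- if (is.finite(model$snr))
          scale * simulate_noise(model, n_pause, seed = NULL)
        else matrix(0, model$m, n_pause)
        chunks[[length(chunks) + 1L]] <- pz
        pos <- pos + n_pause
      }
    }
    structure(
      list(samples = do.call(cbind, chunks),
           intent_log = data.frame(onset = onset,
                                   target = as.integer(intents),
                                   n_samples = n_seg,
                                   pause_samples = n_pause),
           sampling_rate = fs),
      class = "cvep_stream")
  })
}
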