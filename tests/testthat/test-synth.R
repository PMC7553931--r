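# Synthetic EEG generator: determinism, shift structure, SNR and spectrum.

test_that("forward models and trial sets are seed-deterministic", {
  a <- make_forward_model(32, 600, 1.0, 0.5, seed = 7)
  b <- make_forward_model(32, 600, 1.0, 0.5, seed = 7)
  expect_identical(a, b)
  s1 <- simulate_training_set(fm_noisy(), cb4, n_b = 2, seed = 21)
  s2 <- simulate_training_set(fm_noisy(), cb4, n_b = 2, seed = 21)
  expect_identical(s1, s2)
  s3 <- simulate_training_set(fm_noisy(), cb4, n_b = 2, seed = 22)
  expect_false(identical(s1$trials[[1]], s3$trials[[1]]))
})

test_that("single-channel model has unit mixing", {
  fm1 <- make_forward_model(1, 600, 1.0, 0.0, seed = 1)
  expect_equal(abs(fm1$mixing), 1)
})

test_that("trials have the protocol shape and noise-free shift structure", {
  fm <- fm_clean()
  tr <- simulate_trial(fm, cb4, 1, cycles = 2)
  expect_identical(dim(tr), c(8L, 1260L))
  # noise-free trials of one target are identical across calls
  expect_identical(tr, simulate_trial(fm, cb4, 1, cycles = 2, seed = 99))
  # trials of different targets are circular sample-shifts of each other
  for (k in 2:4) {
    tk <- simulate_trial(fm, cb4, k)
    shifted <- cvepr:::col_rotate_within_cycles(
      tk, -cb4$shifts[k] * 10, 630)
    expect_equal(shifted, tr, tolerance = 1e-12)
  }
  expect_error(simulate_trial(fm, cb4, 5), "1..K")
})

test_that("empirical snr matches the requested ratio", {
  fm <- make_forward_model(8, 600, snr = 4, alpha_amp = 0, seed = 3)
  # a long trial (about 30 s) for a stable RMS estimate
  tr <- simulate_trial(fm, cb4, 1, cycles = 28, seed = 5)
  clean <- simulate_trial(fm_clean(seed = 3), cb4, 1, cycles = 28)
  noise <- tr - clean
  ch <- which.max(abs(fm$mixing))
  ratio <- cvepr:::rms(clean[ch, ]) / cvepr:::rms(noise[ch, ])
  expect_equal(ratio, 4, tolerance = 0.1)
})

test_that("alpha contamination creates an 8-12 Hz spectral peak", {
  fm <- make_forward_model(8, 600, snr = 1, alpha_amp = 2, seed = 3)
  noise <- simulate_noise(fm, 600 * 30, seed = 4)
  ch <- which.max(abs(fm$alpha_mixing))
  spec <- Mod(stats::fft(noise[ch, ]))^2
  freqs <- seq(0, by = 1 / 30, length.out = length(spec))
  bp <- function(lo, hi) mean(spec[freqs >= lo & freqs < hi])
  expect_gt(bp(8, 12) / bp(4, 8), 1)
  expect_gt(bp(8, 12) / bp(12, 16), 1)
  # without the contaminant the pink spectrum has no such peak
  fm0 <- make_forward_model(8, 600, snr = 1, alpha_amp = 0, seed = 3)
  noise0 <- simulate_noise(fm0, 600 * 30, seed = 4)
  spec0 <- Mod(stats::fft(noise0[ch, ]))^2
  bp0 <- function(lo, hi) mean(spec0[freqs >= lo & freqs < hi])
  expect_lt(bp0(8, 12) / bp0(4, 8), 1)
})

test_that("evoked amplitude scales linearly with the kernel", {
  fm <- fm_clean()
  fm2 <- fm
  fm2$kernel <- 2 * fm$kernel
  t1 <- simulate_trial(fm, cb4, 1)
  t2 <- simulate_trial(fm2, cb4, 1)
  expect_equal(cvepr:::rms(t2) / cvepr:::rms(t1), 2, tolerance = 1e-12)
})

test_that("training sets follow the block protocol", {
  fm <- fm_clean(m = 4)
  ts32 <- simulate_training_set(fm_clean(m = 2), cb32, n_b = 4, seed = 1)
  expect_length(ts32$trials, 128)
  expect_identical(tabulate(ts32$labels), rep(4L, 32))
  ts4 <- simulate_training_set(fm, cb4, n_b = 6, seed = 1)
  expect_length(ts4$trials, 24)
  cb1 <- build_codebook(K = 1, shift_step = 0)
  ts1 <- simulate_training_set(fm, cb1, n_b = 1, seed = 1)
  expect_length(ts1$trials, 1)
  expect_identical(ts1$labels, 1L)
})

test_that("online streams log non-overlapping intents with pauses", {
  fm <- fm_noisy()
  st <- simulate_online_stream(fm, cb4, intents = c(2, 4), seed = 3,
                               max_duration = 2.1, pause = 1)
  expect_identical(nrow(st$intent_log), 2L)
  seg <- st$intent_log$n_samples[1]
  expect_gte(seg, 2.1 * 600)
  expect_identical(st$intent_log$pause_samples[1], 600L)
  expect_identical(st$intent_log$onset[2],
                   st$intent_log$onset[1] + seg + 600L)
  expect_identical(ncol(st$samples), 2L * (seg + 600L))
  # zero pause makes segments contiguous
  st0 <- simulate_online_stream(fm, cb4, intents = c(1, 2), seed = 3,
                                max_duration = 2.1, pause = 0)
  expect_identical(st0$intent_log$onset[2], st0$intent_log$onset[1] + seg)
  expect_error(simulate_online_stream(fm, cb4, intents = integer(0)),
               "non-empty")
})
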