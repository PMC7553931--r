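# Synchronous and asynchronous target identification.

test_that("correlation scores peak at the matching template", {
  model <- clean_model4()
  X3 <- model$bands[[1]]$templates$class_templates[[3]]
  lambda <- correlation_scores(X3, model)
  expect_identical(which.max(lambda), 3L)
  expect_equal(max(lambda), 1, tolerance = 1e-6)
  expect_error(correlation_scores(X3[, 1:100], model), "too short")
  expect_error(correlation_scores(cbind(X3, X3), model), "longer")
  expect_error(correlation_scores(X3 * 0, model), "degenerate")
})

test_that("a K=1 codebook yields a single score", {
  cb1 <- build_codebook(K = 1, shift_step = 0)
  fm <- fm_clean(m = 4)
  ts1 <- simulate_training_set(fm, cb1, n_b = 2, seed = 2)
  m1 <- train_decoder_model(ts1, cb1, s = 2)
  expect_length(correlation_scores(ts1$trials[[1]], m1), 1)
})

test_that("pearson scoring with s = 1 equals the direct correlation", {
  ts <- clean_set4()
  mp <- train_decoder_model(ts, cb4, s = 1, score_method = "pearson")
  buf <- ts$trials[[2]]
  lambda <- correlation_scores(buf, mp)
  W <- mp$bands[[1]]$W
  for (k in 1:4) {
    ref <- mp$bands[[1]]$templates$class_templates[[k]]
    direct <- abs(cor(drop(crossprod(W, buf)), drop(crossprod(W, ref))))
    expect_equal(lambda[k], direct, tolerance = 1e-10)
  }
})

test_that("classification is exact on noise-free data, including K=32", {
  fm <- fm_clean(m = 6)
  ts32 <- simulate_training_set(fm, cb32, n_b = 1, seed = 2)
  m32 <- train_decoder_model(ts32, cb32, s = 4, beta = 0.1)
  d <- classify_window(simulate_trial(fm, cb32, 7), m32)
  expect_identical(d$class, 7L)
  pred <- vapply(ts32$trials, function(z)
    classify_window(z[, 1:300], m32)$class, integer(1))
  expect_identical(pred, ts32$labels)
})

test_that("scores are invariant to spatial-filter sign flips", {
  model <- clean_model4()
  buf <- simulate_trial(fm_noisy(), cb4, 2, seed = 31)
  base <- correlation_scores(buf, model)
  flipped <- model
  flipped$bands[[1]]$W[, 1] <- -flipped$bands[[1]]$W[, 1]
  flipped$bands[[1]]$proj_templates <- lapply(
    flipped$bands[[1]]$templates$class_templates,
    function(Xk) crossprod(flipped$bands[[1]]$W, Xk))
  expect_equal(correlation_scores(buf, flipped), base, tolerance = 1e-8)
})

test_that("push_block respects the window and shuffle-out mechanics", {
  model <- clean_model4()
  st <- new_decoder_state(model, beta = 1.1)   # unreachable threshold
  fm <- fm_noisy()
  blocks <- simulate_noise(fm, 30 * 100, seed = 5)
  ny_seen <- integer(0)
  for (i in 1:100) {
    r <- push_block(st, blocks[, ((i - 1) * 30 + 1):(i * 30)])
    st <- r$state
    expect_null(r$decision)
    ny_seen <- c(ny_seen, st$n_y)
  }
  # no classification below 150 samples is even possible; buffer capped at n
  expect_identical(ny_seen[1:4], c(30L, 60L, 90L, 120L))
  expect_lte(max(ny_seen), 1260L)
  # at n_y = n the next push shuffles out n/2 columns: 1260 -> 660
  full_at <- which(ny_seen == 1260L)[1]
  expect_identical(ny_seen[full_at + 1L], 660L)
  expect_error(push_block(st, blocks[, 1:10]), "block must be")
})

test_that("asynchronous decisions agree with synchronous classification", {
  model <- clean_model4()
  fm <- fm_clean()
  trial <- simulate_trial(fm, cb4, 4)
  # beta = 0: a decision at the first eligible window, matching the
  # synchronous classification of the same buffer
  st <- new_decoder_state(model, beta = 0)
  dec <- NULL
  for (i in 1:42) {
    r <- push_block(st, trial[, ((i - 1) * 30 + 1):(i * 30)])
    st <- r$state
    if (!is.null(r$decision)) { dec <- r$decision; break }
  }
  expect_identical(dec$window_used, 0.25)
  sync <- classify_window(trial[, 1:150], model)
  expect_identical(dec$class, sync$class)
  expect_equal(dec$scores, sync$scores, tolerance = 1e-12)
  expect_identical(dec$class, 4L)
  # after a decision the buffer is empty
  expect_identical(st$n_y, 0L)
})

test_that("emitted margins strictly exceed beta and clear the buffer", {
  fm <- fm_noisy(snr = 0.8)
  ts <- simulate_training_set(fm, cb4, n_b = 4, seed = 7)
  model <- train_decoder_model(ts, cb4, beta = 0.15)
  stream <- simulate_online_stream(fm, cb4, intents = c(2, 1, 3), seed = 9,
                                   max_duration = 6)
  ses <- run_session(stream, model)
  expect_true(all(ses$margin[ses$decided] > 0.15))
  expect_true(all(ses$selection_time[ses$decided] ==
                    ses$window_used[ses$decided] + 1))
})

test_that("noise-only false positives decrease as beta increases", {
  fm <- fm_noisy(snr = 0.5)
  ts <- simulate_training_set(fm, cb4, n_b = 4, seed = 3)
  model <- train_decoder_model(ts, cb4)
  noise <- simulate_noise(fm, 30 * 600, seed = 13)   # 30 s of rest EEG
  counts <- vapply(c(0.05, 0.15, 0.40), function(beta) {
    st <- new_decoder_state(model, beta = beta)
    n_dec <- 0L
    for (i in seq_len(ncol(noise) %/% 30)) {
      r <- push_block(st, noise[, ((i - 1) * 30 + 1):(i * 30)])
      st <- r$state
      if (!is.null(r$decision)) n_dec <- n_dec + 1L
    }
    n_dec
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], counts[1])
})

test_that("an unreachable threshold preserves the non-control state", {
  model <- clean_model4()
  fm <- fm_clean()
  stream <- simulate_online_stream(fm, cb4, intents = 2, seed = 1,
                                   max_duration = 3)
  ses <- run_session(stream, model, beta = 1.1)
  expect_false(ses$decided[1])
  expect_true(is.na(ses$class[1]))
})

test_that("noise-free sessions recover every intent", {
  model <- clean_model4()
  fm <- fm_clean()
  intents <- c(3, 1, 4, 2, 2)
  stream <- simulate_online_stream(fm, cb4, intents = intents, seed = 17,
                                   max_duration = 4)
  ses <- run_session(stream, model)
  expect_true(all(ses$decided))
  expect_equal(ses$class, intents)
  expect_true(all(ses$correct))
})
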