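# CCA solver and the spatial-filter / full-model training path.

test_that("cca recovers perfect and univariate correlations", {
  set.seed(1)
  X <- matrix(rnorm(3 * 80), 3)
  res <- cca(X, X)
  expect_equal(res$rho, rep(1, 3), tolerance = 1e-6)
  expect_true(all(diff(res$rho) <= 1e-12))
  # 1-D case equals |Pearson|
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  expect_equal(cca(x, y)$rho, abs(cor(x, y)), tolerance = 1e-6)
})

test_that("independent noise gives small correlations vanishing with n", {
  set.seed(2)
  mean_rho <- vapply(c(50, 200, 1600), function(n) {
    mean(replicate(8, cca(matrix(rnorm(2 * n), 2),
                          matrix(rnorm(2 * n), 2))$rho[1]))
  }, numeric(1))
  expect_true(all(diff(mean_rho) < 0))
  expect_lt(mean_rho[3], 0.1)
})

test_that("solver matches dense grid-search maximization on 2x2 instances", {
  set.seed(3)
  for (i in 1:4) {
    X <- matrix(rnorm(2 * 50), 2)
    Y <- 0.5 * X[sample(2), ] + matrix(rnorm(2 * 50), 2)
    expect_equal(cca(X, Y)$rho[1], grid_rho1_2x2(X, Y), tolerance = 1e-3)
  }
})

test_that("cca is scale-invariant and yields uncorrelated variate pairs", {
  set.seed(4)
  X <- matrix(rnorm(3 * 200), 3)
  Y <- matrix(rnorm(4 * 200), 4)
  base <- cca(X, Y)
  scaled <- cca(5 * X, -0.2 * Y)
  expect_equal(base$rho, scaled$rho, tolerance = 1e-8)
  # canonical variates: cross-correlation matrix is diag(rho)
  U <- crossprod(X - rowMeans(X), base$a)
  V <- crossprod(Y - rowMeans(Y), base$b)
  cc <- abs(cor(U, V))
  expect_equal(diag(cc), base$rho, tolerance = 1e-6)
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-6)
  expect_error(cca(matrix(0, 2, 50), Y[, 1:50]), "singular")
  expect_error(cca(X[, 1:2], Y[, 1:2]), "observations")
})

test_that("spatial filters project noise-free trials onto their template", {
  ts <- clean_set4()
  aligned <- align_trials(ts, cb4)
  zbar <- grand_average(aligned)
  flt <- train_spatial_filters(aligned, zbar, s = 4)
  expect_identical(dim(flt$W), c(8L, 4L))
  expect_equal(flt$rho[1], 1, tolerance = 1e-6)
  proj_t <- drop(crossprod(flt$W[, 1, drop = FALSE], aligned[[1]]))
  proj_z <- drop(crossprod(flt$W[, 1, drop = FALSE], zbar))
  expect_equal(abs(cor(proj_t, proj_z)), 1, tolerance = 1e-6)
  # single-channel data: the only filter direction is [1] up to sign/scale
  fm1 <- fm_clean(m = 1)
  ts1 <- simulate_training_set(fm1, cb4, n_b = 2, seed = 2)
  al1 <- align_trials(ts1, cb4)
  f1 <- train_spatial_filters(al1, grand_average(al1), s = 1)
  expect_identical(dim(f1$W), c(1L, 1L))
  expect_gt(abs(f1$W[1, 1]), 0)
  expect_error(train_spatial_filters(al1, grand_average(al1), s = 2),
               "exceeds")
})

test_that("filters are invariant (up to sign) to trial order", {
  ts <- simulate_training_set(fm_noisy(), cb4, n_b = 2, seed = 8)
  aligned <- align_trials(ts, cb4)
  zbar <- grand_average(aligned)
  W1 <- train_spatial_filters(aligned, zbar, s = 2)$W
  perm <- rev(seq_along(aligned))
  W2 <- train_spatial_filters(aligned[perm], zbar, s = 2)$W
  for (i in 1:2)
    expect_equal(abs(W1[, i] / sqrt(sum(W1[, i]^2))),
                 abs(W2[, i] / sqrt(sum(W2[, i]^2))), tolerance = 1e-6)
})

test_that("full training self-classifies noise-free data and round-trips", {
  model <- clean_model4()
  ts <- clean_set4()
  pred <- vapply(ts$trials, function(z) classify_window(z, model)$class,
                 integer(1))
  expect_identical(pred, ts$labels)
  # missing-class coverage error
  sub <- ts
  keep <- ts$labels != 3
  sub$trials <- ts$trials[keep]; sub$labels <- ts$labels[keep]
  expect_error(train_decoder_model(sub, cb4), "missing")
  # save/load is bit-identical
  path <- withr::local_tempfile(fileext = ".rds")
  write_decoder_model(model, path)
  expect_identical(read_decoder_model(path), model)
})
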