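# Shared small fixtures, built in code. Trial sets use a reduced montage
# (8 channels) so the suite stays fast; the stimulation protocol itself
# (63-bit code, 60 Hz update, 600 Hz sampling, 2-cycle trials) is the
# default one.

cb4 <- build_codebook(K = 4, shift_step = 4)
cb32 <- build_codebook(K = 32, shift_step = 2)

fm_clean <- function(m = 8, seed = 3)
  make_forward_model(m = m, snr = Inf, alpha_amp = 0, seed = seed)

fm_noisy <- function(m = 8, snr = 0.5, alpha_amp = 1, seed = 3)
  make_forward_model(m = m, snr = snr, alpha_amp = alpha_amp, seed = seed)

# cached noise-free 4-target model + training set (many tests reuse it)
clean_set4 <- local({
  ts <- NULL
  function() {
    if (is.null(ts)) ts <<- simulate_training_set(fm_clean(), cb4, n_b = 2,
                                                  seed = 11)
    ts
  }
})

clean_model4 <- local({
  mod <- NULL
  function() {
    if (is.null(mod)) mod <<- train_decoder_model(clean_set4(), cb4,
                                                  bank = NULL, beta = 0.15)
    mod
  }
})

# independent dense grid-search maximization of the canonical correlation
# for 2 x 2-variable instances (unit-norm weights parameterized by angle)
grid_rho1_2x2 <- function(X, Y, n_grid = 700) {
  theta <- seq(0, pi, length.out = n_grid)
  A <- rbind(cos(theta), sin(theta))
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  U <- crossprod(Xc, A)                      # n x n_grid canonical variates
  V <- crossprod(Yc, A)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  max(abs(crossprod(U, V)))
}
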