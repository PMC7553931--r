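# Canonical correlation analysis with all canonical variate pairs, and the
# CCA-based spatial-filter ensemble. CCA between X (m1 x n) and Y (m2 x n)
# finds weight pairs (a_i, b_i) maximizing the correlation of the canonical
# variates X'a and Y'b, successive pairs being uncorrelated with earlier
# ones; it yields min(m1, m2) correlations sorted descending. The solver
# whitens both covariance matrices (eigendecomposition with a small ridge)
# and takes the SVD of the whitened cross-covariance.

#' Canonical correlation analysis
#'
#' @param X,Y Matrices with variables in rows and `n` observations in
#'   columns; rows are centred internally.
#' @param reg Ridge added to each covariance as `reg * mean(diag(C))`;
#'   guards near-singular covariances from short buffers.
#' @return A `cvep_cca` object: `rho` (descending canonical correlations in
#'   `[0, 1]`), `a` (`m1 x m` left weights), `b` (`m2 x m` right weights),
#'   `m = min(m1, m2)`.
#' @examples
#' x <- matrix(rnorm(40), 2)
#' cca(x, x)$rho       # both correlations are 1
#' @export
cca <- function(X, Y, reg = 1e-9) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of columns")
  if (n <= max(nrow(X), nrow(Y)))
    stop("need more observations (columns) than variables (rows)")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / (n - 1)
  Cyy <- tcrossprod(Yc) / (n - 1)
  Cxy <- tcrossprod(Xc, Yc) / (n - 1)
  if (all(diag(Cxx) == 0) || all(diag(Cyy) == 0))
    stop("singular input: a variable set has zero variance")
  isqrt <- function(C) {
    C <- C + diag(reg * mean(diag(C)), nrow(C))
    e <- eigen(C, symmetric = TRUE)
    vals <- pmax(e$values, reg * mean(diag(C)))
    e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  Wx <- isqrt(Cxx)
  Wy <- isqrt(Cyy)
  K <- Wx %*% Cxy %*% Wy
  sv <- svd(K)
  m <- min(nrow(X), nrow(Y))
  structure(
    list(rho = pmin(pmax(sv$d[seq_len(m)], 0), 1),
         a = Wx %*% sv$u[, seq_len(m), drop = FALSE],
         b = Wy %*% sv$v[, seq_len(m), drop = FALSE],
         m = m),
    class = "cvep_cca")
}

# First canonical correlation only (score path hot spot).
rho1 <- function(X, Y, reg = 1e-9) cca(X, Y, reg = reg)$rho[1]

#' Train the CCA spatial-filter ensemble
#'
#' Concatenates the N aligned trials into `[Z_1 ... Z_N]` and N copies of
#' the grand average into `[Zbar ... Zbar]`, runs CCA between the two, and
#' keeps the first `s` left weight vectors as spatial filters.
#'
#' @param aligned List of aligned `m x n` trial matrices.
#' @param zbar Grand-average matrix.
#' @param s Number of canonical variates kept as filters (default 4).
#' @return List with `W` (`m x s` filter matrix) and `rho` (all canonical
#'   correlations; `rho[1]` feeds the filter-bank weights).
#' @export
train_spatial_filters <- function(aligned, zbar, s = 4) {
  if (length(aligned) < 1) stop("need at least one aligned trial")
  Xt <- do.call(cbind, aligned)
  Yt <- do.call(cbind, rep(list(zbar), length(aligned)))
  res <- cca(Xt, Yt)
  if (s > ncol(res$a))
    stop("`s` exceeds the number of available canonical variates (",
         ncol(res$a), ")")
  list(W = res$a[, seq_len(s), drop = FALSE], rho = res$rho)
}

#' Train a complete decoder model
#'
#' For each sub-band (or once on broadband data when `bank` is `NULL`, the
#' "standard" method): filter all trials, align them by code phase, average,
#' build class templates and the spatial-filter ensemble, and precompute the
#' filter-projected templates used by the scoring path. With a filter bank,
#' per-band weights `a_j` are the normalized first canonical correlations.
#'
#' @param trials A labelled `cvep_trialset` covering all `K` classes.
#' @param codebook A `cvep_codebook`.
#' @param bank A `cvep_filterbank`, or `NULL` for the standard single-band
#'   method on unfiltered data.
#' @param s Number of spatial filters (canonical variates), default 4.
#' @param beta Default decision threshold stored with the model (0.15 and
#'   0.1 are the protocol defaults for 4 and 32 targets).
#' @param score_method How Eq.-style correlation between stacked projected
#'   signals is computed: first canonical correlation (default) or
#'   flattened absolute Pearson correlation.
#' @return A `cvep_decoder_model`.
#' @export
train_decoder_model <- function(trials, codebook, bank = NULL, s = 4,
                                beta = if (codebook$K <= 4) 0.15 else 0.1,
                                score_method = c("canonical", "pearson")) {
  stopifnot(inherits(trials, "cvep_trialset"),
            inherits(codebook, "cvep_codebook"))
  score_method <- match.arg(score_method)
  present <- sort(unique(trials$labels))
  if (!identical(present, seq_len(codebook$K)))
    stop("training data must contain every class 1..K; missing: ",
         paste(setdiff(seq_len(codebook$K), present), collapse = ", "))
  if (s > trials$m) stop("`s` cannot exceed the number of channels")
  spb <- samples_per_bit(trials$sampling_rate, codebook$update_rate)
  n_bands <- if (is.null(bank)) 1L else length(bank$filters)

  band_models <- vector("list", n_bands)
  rhos <- numeric(n_bands)
  for (j in seq_len(n_bands)) {
    ts_j <- trials
    if (!is.null(bank))
      ts_j$trials <- lapply(trials$trials, apply_subband, bank = bank, j = j)
    aligned <- align_trials(ts_j, codebook)
    zbar <- grand_average(aligned)
    flt <- train_spatial_filters(aligned, zbar, s = s)
    tmpl <- make_class_templates(zbar, codebook, spb)
    proj <- lapply(tmpl$class_templates,
                   function(Xk) crossprod(flt$W, Xk))
    band_models[[j]] <- list(W = flt$W, templates = tmpl,
                             proj_templates = proj, rho1 = flt$rho[1])
    rhos[j] <- flt$rho[1]
  }
  weights <- if (n_bands == 1L) 1 else compute_band_weights(rhos)

  structure(
    list(bands = band_models, bank = bank, weights = weights,
         band_rhos = rhos, codebook = codebook,
         sampling_rate = trials$sampling_rate, m = trials$m, n = trials$n,
         s = s, beta = beta, score_method = score_method),
    class = "cvep_decoder_model")
}

#' @export
print.cvep_decoder_model <- function(x, ...) {
  cat("c-VEP decoder model: K = ", x$codebook$K, ", ", x$m, " channels @ ",
      x$sampling_rate, " Hz, s = ", x$s, " spatial filters, ",
      length(x$bands), " band(s), beta = ", x$beta, "\n", sep = "")
  if (length(x$bands) > 1)
    cat("  band weights: ", paste(signif(x$weights, 4), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Save or load a trained decoder model
#'
#' Serialized with R's native format; arrays round-trip bit-identically.
#'
#' @param model A `cvep_decoder_model`.
#' @param path File path.
#' @return `read_decoder_model` returns the restored model.
#' @export
write_decoder_model <- function(model, path) {
  stopifnot(inherits(model, "cvep_decoder_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_decoder_model
#' @export
read_decoder_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cvep_decoder_model"))
    stop("file does not contain a decoder model")
  model
}
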