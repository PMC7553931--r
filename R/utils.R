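# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' random-number state afterwards, so seeded simulations never disturb the
#' global stream. A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

# Circular left rotation of the columns of a matrix; negative k rotates right.
col_rotate <- function(mat, k) {
  n <- ncol(mat)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(mat)
  mat[, c((k + 1L):n, 1L:k), drop = FALSE]
}

# Apply col_rotate independently within consecutive blocks of `cycle_len`
# columns, keeping cycle boundaries fixed.
col_rotate_within_cycles <- function(mat, k, cycle_len) {
  n <- ncol(mat)
  if (n %% cycle_len != 0)
    stop("number of columns (", n, ") not divisible by cycle length (",
         cycle_len, ")")
  n_cycles <- n %/% cycle_len
  idx <- integer(0)
  k <- ((k %% cycle_len) + cycle_len) %% cycle_len
  base <- if (k == 0) 1L:cycle_len else c((k + 1L):cycle_len, 1L:k)
  for (cy in seq_len(n_cycles)) idx <- c(idx, (cy - 1L) * cycle_len + base)
  mat[, idx, drop = FALSE]
}

# Small named-argument checker used by user-facing entry points.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("`", name, "` must be a positive number")
  invisible(x)
}
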