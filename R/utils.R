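`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so package functions never leak random state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' Reflect an index vector into [1, n] (mirror boundary, no edge repetition
#' beyond the first bounce; falls back to clamping for extreme overshoot).
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  as.integer(j + 1L)
}

clamp_index <- function(i, n) pmin(pmax(i, 1L), n)

#' Reflection-pad an H x W x C array (or H x W matrix).
#' @noRd
reflect_pad <- function(x, top, left, bottom, right) {
  d <- dim(x)
  ri <- reflect_index(seq_len(d[1] + top + bottom) - top, d[1])
  ci <- reflect_index(seq_len(d[2] + left + right) - left, d[2])
  if (length(d) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}

#' Row-wise softmax of an N x K matrix, numerically stabilised.
#' @noRd
softmax_rows <- function(z) {
  m <- z[, 1]
  for (k in seq_len(ncol(z))[-1]) m <- pmax(m, z[, k])
  e <- exp(z - m)
  e / rowSums(e)
}

#' Gaussian low-pass filter of a matrix via FFT (circular boundary).
#' @noRd
fft_lowpass <- function(x, sigma) {
  h <- nrow(x); w <- ncol(x)
  fy <- c(0:floor(h / 2), -((ceiling(h / 2) - 1):1)) / h
  fx <- c(0:floor(w / 2), -((ceiling(w / 2) - 1):1)) / w
  g <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / (h * w)
}

#' Band-passed unit-variance noise field with characteristic granule size
#' `scale_px`; the generator behind per-class canopy texture.
#' @noRd
bandpass_noise <- function(h, w, scale_px) {
  n <- matrix(rnorm(h * w), h, w)
  f <- fft_lowpass(n, scale_px / 2) - fft_lowpass(n, scale_px)
  s <- sd(f)
  if (s < .Machine$double.eps) return(matrix(0, h, w))
  f / s
}
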