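# Internal helpers shared across modules.

# Centered FFT frequencies (cycles per unit), base-R equivalent of numpy fftfreq.
fft_freq <- function(n, d = 1) {
  k <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)
  k / (n * d)
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular shift of a matrix by one step along rows (i) or columns (j).
shift_rows <- function(m, by = 1L) {
  n <- nrow(m)
  m[((seq_len(n) - 1L + by) %% n) + 1L, , drop = FALSE]
}

shift_cols <- function(m, by = 1L) {
  n <- ncol(m)
  m[, ((seq_len(n) - 1L + by) %% n) + 1L, drop = FALSE]
}

# Derive a reproducible 32-bit sub-seed from a master seed and an index.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 30269) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Random walk from `start` with the given steps, reflected into [lim[1],
# lim[2]] by triangle folding (vectorized equivalent of reflecting at the
# boundaries step by step).
reflect_walk <- function(start, steps, lim) {
  x <- start + cumsum(c(0, steps))
  R <- lim[2] - lim[1]
  y <- (x - lim[1]) %% (2 * R)
  lim[1] + pmin(y, 2 * R - y)
}
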