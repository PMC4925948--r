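# Separable Gaussian-derivative filtering and interpolation primitives shared
# by the enhancement and wall-delineation stages. Borders use edge replication.

gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(order + 1L,
    g,
    -x / sigma^2 * g,                     # d/dx
    (x^2 - sigma^2) / sigma^4 * g)        # d2/dx2
  # truncation leaves derivative kernels with a small DC response; remove it
  # so constant image offsets are exactly invisible to the derivatives
  if (order > 0L) k <- k - mean(k)
  k
}

# Convolve columns of `m` with kernel `k` (i.e. along the row index),
# replicating edge rows. Vectorized over all columns at once.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * pad[seq_len(n) + (length(k) - j), , drop = FALSE]
  out
}

# Separable filter: `ky` along rows (vertical axis), `kx` along columns.
conv_sep <- function(m, ky, kx) t(conv_cols(t(conv_cols(m, ky)), kx))

# Scale-normalized Gaussian-derivative images. `dy` differentiates along the
# row axis, `dx` along the column axis; gamma-normalization by sigma^(dy+dx).
gaussian_deriv <- function(m, sigma, dy = 0L, dx = 0L) {
  conv_sep(m, gaussian_kernel(sigma, dy), gaussian_kernel(sigma, dx)) *
    sigma^(dy + dx)
}

# Bilinear interpolation of matrix `m` at sub-pixel (row, col) positions.
# Positions are clamped to the image domain; `outside` flags clamped queries.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  outside <- row < 1 | row > nr | col < 1 | col > nc
  r <- pmin(pmax(row, 1), nr)
  c <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
       (1 - fr) * fc       * m[cbind(r0, c0 + 1)] +
       fr       * (1 - fc) * m[cbind(r0 + 1, c0)] +
       fr       * fc       * m[cbind(r0 + 1, c0 + 1)]
  attr(v, "outside") <- outside
  v
}
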