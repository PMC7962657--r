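# Separable filtering primitives shared by the curvature, edge and synthetic
# modules. Borders are handled by replication so that derivative estimates do
# not see an artificial step at the image boundary.

gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# First-derivative-of-Gaussian kernel, normalized so that convolving a unit
# ramp yields exactly 1 (discrete counterpart of d/dx).
gaussian_deriv_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- -x * g
  k <- k / sum(x^2 * g / sum(g)) / sum(g)
  (k - rev(k)) / 2  # force exact antisymmetry (zero response to constants)
}

# convolve along rows (dim = 2, the x/column axis) or columns (dim = 1, the
# y/row axis) with edge replication
convolve_1d <- function(img, kernel, dim) {
  r <- (length(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  if (dim == 2L) {
    padded <- img[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
    for (k in seq_along(kernel)) {
      out <- out + kernel[k] * padded[, (k - 1L) + seq_len(w), drop = FALSE]
    }
  } else {
    padded <- img[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
    for (k in seq_along(kernel)) {
      out <- out + kernel[k] * padded[(k - 1L) + seq_len(h), , drop = FALSE]
    }
  }
  out
}

# true 2-D convolution out[j] = sum_o kx(o) img[j - o], separable
filter_sep <- function(img, kx, ky) {
  convolve_1d(convolve_1d(img, rev(kx), 2L), rev(ky), 1L)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gaussian_kernel(sigma)
  filter_sep(img, g, g)
}

# central differences with replicate borders
central_diff <- function(img, dim) {
  h <- nrow(img); w <- ncol(img)
  if (dim == 2L) {
    if (w == 1L) return(matrix(0, h, w))
    right <- img[, c(2:w, w), drop = FALSE]
    left  <- img[, c(1, 1:(w - 1)), drop = FALSE]
  } else {
    if (h == 1L) return(matrix(0, h, w))
    right <- img[c(2:h, h), , drop = FALSE]
    left  <- img[c(1, 1:(h - 1)), , drop = FALSE]
  }
  (right - left) / 2
}
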