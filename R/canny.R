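#' Canny edge map of a response image
#'
#' Classic Canny detector used to place the knots that segment the scan lines:
#' Gaussian smoothing, central-difference gradients, non-maximum suppression
#' perpendicular to the local gradient, and hysteresis thresholding. The
#' hysteresis levels are specified as quantiles of the nonzero gradient
#' magnitudes rather than absolute values, so the detector adapts to the
#' dynamic range of the curvature response it runs on.
#'
#' @param response Numeric matrix (typically a vein response map).
#' @param low,high Hysteresis thresholds as quantile probabilities of the
#'   nonzero gradient magnitudes, `0 <= low < high <= 1`. Defaults 0.7 / 0.9.
#' @param sigma Smoothing scale in pixels before differentiation (default 1.5).
#' @return An integer 0/1 matrix of the same shape.
#' @export
edge_map <- function(response, low = 0.7, high = 0.9, sigma = 1.5) {
  stopifnot(is.matrix(response), all(is.finite(response)))
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high ||
      high > 1) {
    stop("invalid hysteresis thresholds: need 0 <= low < high <= 1",
         call. = FALSE)
  }
  h <- nrow(response); w <- ncol(response)
  sm <- gaussian_blur(response, sigma)
  gx <- central_diff(sm, 2L)
  gy <- central_diff(sm, 1L)
  mag <- sqrt(gx^2 + gy^2)
  nz <- mag[mag > 0]
  if (length(nz) == 0L) {
    return(matrix(0L, h, w))
  }
  thr_low <- stats::quantile(nz, low, names = FALSE)
  thr_high <- stats::quantile(nz, high, names = FALSE)

  # non-maximum suppression: quantize gradient direction to one of 4 sectors
  # and keep pixels that dominate both neighbours across the edge
  ang <- atan2(gy, gx)              # (-pi, pi]
  sector <- floor(((ang / pi * 4) %% 8 + 0.5)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift_mat <- function(m, dr, dc, fill = 0) {
    out <- matrix(fill, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
  nbr <- list(
    list(c(0L, 1L),  c(0L, -1L)),   # sector 0: gradient ~ horizontal
    list(c(1L, 1L),  c(-1L, -1L)),  # sector 1: diagonal
    list(c(1L, 0L),  c(-1L, 0L)),   # sector 2: vertical
    list(c(1L, -1L), c(-1L, 1L))    # sector 3: anti-diagonal
  )
  keep <- matrix(FALSE, h, w)
  for (s in 0:3) {
    n1 <- shift_mat(mag, nbr[[s + 1]][[1]][1], nbr[[s + 1]][[1]][2])
    n2 <- shift_mat(mag, nbr[[s + 1]][[2]][1], nbr[[s + 1]][[2]][2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  cand <- keep & mag >= thr_low
  strong <- cand & mag >= thr_high
  if (!any(strong)) {
    return(matrix(0L, h, w))
  }

  # hysteresis: grow strong edges through 8-connected candidate pixels
  cur <- strong
  repeat {
    dil <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      dil <- dil | shift_mat(cur, dr, dc, fill = FALSE)
    }
    nxt <- dil & cand
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  matrix(as.integer(cur), h, w)
}
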