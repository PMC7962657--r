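#' Database crop/resize presets
#'
#' Named preparation presets for the finger-vein databases the pipeline is
#' normally run on: boundary crops that strip device frames and shadows, an
#' optional 90-degree rotation for fingertip-down captures, and a bicubic
#' downscale. `"none"` leaves images untouched.
#'
#' @param name One of `"hkpu"`, `"mmcbnu"`, `"fvusm"`, `"zscfv"`, `"none"`,
#'   or `NULL` to construct a custom preset from the remaining arguments.
#' @param crop_top,crop_bottom,crop_left,crop_right Non-negative pixel crops.
#' @param rotate_deg Rotation in degrees, a multiple of 90 (counter-clockwise).
#' @param scale_factor Resize ratio in `(0, 1]`.
#' @return A list of class `"fv_preset"`.
#' @export
#' @examples
#' db_preset("mmcbnu")
db_preset <- function(name = NULL, crop_top = 0L, crop_bottom = 0L,
                      crop_left = 0L, crop_right = 0L, rotate_deg = 0L,
                      scale_factor = 1) {
  presets <- list(
    hkpu   = list(crop_top = 30L, crop_bottom = 10L, crop_left = 30L,
                  crop_right = 50L, rotate_deg = 0L, scale_factor = 1 / 2),
    mmcbnu = list(crop_top = 5L, crop_bottom = 5L, crop_left = 5L,
                  crop_right = 5L, rotate_deg = 0L, scale_factor = 1 / 4),
    fvusm  = list(crop_top = 150L, crop_bottom = 150L, crop_left = 5L,
                  crop_right = 70L, rotate_deg = 90L, scale_factor = 1 / 2),
    zscfv  = list(crop_top = 20L, crop_bottom = 20L, crop_left = 20L,
                  crop_right = 20L, rotate_deg = 0L, scale_factor = 1 / 2),
    none   = list(crop_top = 0L, crop_bottom = 0L, crop_left = 0L,
                  crop_right = 0L, rotate_deg = 0L, scale_factor = 1)
  )
  if (!is.null(name)) {
    name <- match.arg(name, names(presets))
    p <- presets[[name]]
    p$name <- name
  } else {
    p <- list(crop_top = as.integer(crop_top),
              crop_bottom = as.integer(crop_bottom),
              crop_left = as.integer(crop_left),
              crop_right = as.integer(crop_right),
              rotate_deg = as.integer(rotate_deg),
              scale_factor = scale_factor)
    p$name <- "custom"
  }
  stopifnot(p$crop_top >= 0, p$crop_bottom >= 0, p$crop_left >= 0,
            p$crop_right >= 0, p$rotate_deg %% 90 == 0,
            p$scale_factor > 0, p$scale_factor <= 1)
  structure(p, class = "fv_preset")
}

# counter-clockwise quarter-turn rotations
rotate90k <- function(img, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) img <- t(img)[ncol(img):1, , drop = FALSE]
  img
}

#' Apply a database preset: rotate, crop, bicubic resize
#'
#' Rotation (if any) is applied first, then the boundary crops, then a
#' bicubic (Catmull-Rom) resize. The output dimension for a side of `n`
#' pixels at scale `s < 1` is `floor(n * s) + 1` — the rule that reproduces
#' the published post-scaling sizes of all four supported databases
#' simultaneously; at `s = 1` the image passes through unchanged.
#'
#' @param img Numeric intensity matrix.
#' @param preset An [db_preset()] object.
#' @return The prepared intensity matrix.
#' @export
crop_and_scale <- function(img, preset = db_preset("none")) {
  stopifnot(is.matrix(img))
  img <- rotate90k(img, preset$rotate_deg %/% 90L)
  h <- nrow(img); w <- ncol(img)
  if (preset$crop_top + preset$crop_bottom >= h ||
      preset$crop_left + preset$crop_right >= w) {
    stop("crop exceeds image size", call. = FALSE)
  }
  img <- img[(preset$crop_top + 1L):(h - preset$crop_bottom),
             (preset$crop_left + 1L):(w - preset$crop_right), drop = FALSE]
  s <- preset$scale_factor
  if (s == 1) {
    return(img)
  }
  out_h <- floor(nrow(img) * s) + 1L
  out_w <- floor(ncol(img) * s) + 1L
  resize_bicubic(img, out_h, out_w)
}

# Catmull-Rom (Keys, a = -1/2) cubic interpolation weight
cubic_weight <- function(t) {
  a <- -0.5
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# dense interpolation matrix mapping n input samples to n_out output samples
# (corner-aligned grid); rows sum to 1
cubic_interp_matrix <- function(n, n_out) {
  if (n == 1L) return(matrix(1, n_out, 1L))
  x <- if (n_out == 1L) (n + 1) / 2 else seq(1, n, length.out = n_out)
  m <- matrix(0, n_out, n)
  base <- floor(x)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 1L), n)
    wgt <- cubic_weight(x - (base + k))
    m[cbind(seq_len(n_out), idx)] <- m[cbind(seq_len(n_out), idx)] + wgt
  }
  m / rowSums(m)
}

resize_bicubic <- function(img, out_h, out_w) {
  a <- cubic_interp_matrix(nrow(img), out_h)
  b <- cubic_interp_matrix(ncol(img), out_w)
  a %*% img %*% t(b)
}

#' Locate a simplified finger region of interest
#'
#' The finger appears as a bright horizontal band between two near-horizontal
#' contours. The image is split into four quadrants; in each quadrant a
#' three-level dynamic threshold (fractions of the quadrant's maximum
#' gradient magnitude, highest first) selects per-column edge candidates
#' whose gradient is predominantly vertical, and the strongest candidate per
#' column becomes a contour point. The upper contour is assembled across the
#' two top quadrants and the lower contour across the two bottom quadrants;
#' the ROI is the bounding box between the two contours. If no contour point
#' is found on either side, the whole image is returned with `fallback =
#' TRUE`.
#'
#' @param img Numeric intensity matrix, at least 32 x 32.
#' @param levels Decreasing threshold fractions of the per-quadrant maximum
#'   gradient magnitude (default `c(0.8, 0.6, 0.4)`).
#' @param sigma Pre-smoothing scale for the gradients (default 1.5).
#' @return A list of class `"fv_roi"`: `bbox` (`c(row0, col0, row1, col1)`,
#'   1-based inclusive), `mask` (0/1 matrix, nonzero inside the bbox),
#'   `fallback`, and the per-column `upper` / `lower` contour rows (NA where
#'   not found).
#' @export
locate_roi <- function(img, levels = c(0.8, 0.6, 0.4), sigma = 1.5) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  if (h < 32L || w < 32L) {
    stop("image too small for ROI localization (need >= 32 x 32)",
         call. = FALSE)
  }
  sm <- gaussian_blur(img, sigma)
  gx <- central_diff(sm, 2L)
  gy <- central_diff(sm, 1L)
  mag <- sqrt(gx^2 + gy^2)
  horiz <- abs(gy) >= abs(gx)  # near-horizontal edge: vertical gradient

  half_r <- h %/% 2L
  half_c <- w %/% 2L
  upper <- rep(NA_integer_, w)
  lower <- rep(NA_integer_, w)
  quads <- list(
    list(rows = 1L:half_r, cols = 1L:half_c, side = "upper"),
    list(rows = 1L:half_r, cols = (half_c + 1L):w, side = "upper"),
    list(rows = (half_r + 1L):h, cols = 1L:half_c, side = "lower"),
    list(rows = (half_r + 1L):h, cols = (half_c + 1L):w, side = "lower")
  )
  for (q in quads) {
    qmag <- mag[q$rows, q$cols, drop = FALSE]
    qok <- horiz[q$rows, q$cols, drop = FALSE]
    qmax <- max(qmag)
    if (qmax == 0) next
    for (ci in seq_along(q$cols)) {
      for (lev in levels) {
        sel <- qok[, ci] & qmag[, ci] >= lev * qmax
        if (any(sel)) {
          r <- q$rows[which(sel)[which.max(qmag[sel, ci])]]
          if (q$side == "upper") upper[q$cols[ci]] <- r
          else lower[q$cols[ci]] <- r
          break
        }
      }
    }
  }

  if (all(is.na(upper)) || all(is.na(lower))) {
    mask <- matrix(1L, h, w)
    return(structure(list(bbox = c(1L, 1L, h, w), mask = mask,
                          fallback = TRUE, upper = upper, lower = lower),
                     class = "fv_roi"))
  }
  r0 <- as.integer(round(stats::median(upper, na.rm = TRUE)))
  r1 <- as.integer(round(stats::median(lower, na.rm = TRUE)))
  r0 <- max(1L, min(r0, h)); r1 <- max(r0, min(r1, h))
  mask <- matrix(0L, h, w)
  mask[r0:r1, ] <- 1L
  structure(list(bbox = c(r0, 1L, r1, w), mask = mask, fallback = FALSE,
                 upper = upper, lower = lower),
            class = "fv_roi")
}
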