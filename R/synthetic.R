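#' Specification of a synthetic vein-image dataset
#'
#' Parameters of the seeded generator that emulates near-infrared finger
#' captures: a bright finger band on a dark border, dark smooth curvilinear
#' vein networks with Gaussian cross-profiles, an illumination gradient,
#' blur, and additive noise. Intra-class variation comes from small rigid
#' shifts/rotations of the vein skeleton and fresh noise draws; inter-class
#' variation from independently drawn skeletons.
#'
#' Defaults describe a low-contrast regime comparable to scaled finger-vein
#' database images: 120 x 180 pixels, vein contrast 30 grey levels on a
#' ~160-level finger region, noise standard deviation 8 grey levels, shifts
#' up to 6 px and rotations up to 2 degrees between captures of the same
#' finger.
#'
#' @param n_classes Number of finger classes (>= 2).
#' @param m_images Images per class (>= 2).
#' @param height,width Image size in pixels.
#' @param background Finger-region intensity (8-bit units).
#' @param border Intensity of the dark border outside the finger band.
#' @param contrast Vein-vs-background intensity drop (8-bit units).
#' @param illum_amplitude Peak-to-peak amplitude of the linear illumination
#'   gradient (8-bit units).
#' @param blur_sigma Gaussian blur scale (px).
#' @param noise_sd Additive Gaussian noise standard deviation (8-bit units).
#' @param shift_px Maximum absolute intra-class shift (px, per axis).
#' @param rotation_deg Maximum absolute intra-class rotation (degrees).
#' @param seed Master seed; all class and instance seeds derive from it.
#' @return A list of class `"fv_dataset_spec"`.
#' @export
dataset_spec <- function(n_classes = 20L, m_images = 6L,
                         height = 120L, width = 180L,
                         background = 160, border = 60, contrast = 30,
                         illum_amplitude = 20, blur_sigma = 1.2,
                         noise_sd = 8, shift_px = 6, rotation_deg = 2,
                         seed = 1L) {
  stopifnot(n_classes >= 2L, m_images >= 2L, height >= 32L, width >= 32L,
            contrast >= 0, noise_sd >= 0, shift_px >= 0, rotation_deg >= 0,
            blur_sigma >= 0)
  structure(
    list(n_classes = as.integer(n_classes), m_images = as.integer(m_images),
         height = as.integer(height), width = as.integer(width),
         background = background, border = border, contrast = contrast,
         illum_amplitude = illum_amplitude, blur_sigma = blur_sigma,
         noise_sd = noise_sd, shift_px = shift_px,
         rotation_deg = rotation_deg, seed = as.integer(seed)),
    class = "fv_dataset_spec"
  )
}

#' Draw a vein-network class specification
#'
#' A finger class is a set of 3-7 smooth, roughly longitudinal polylines
#' (random-walk control points smoothed by splines) with per-vein widths
#' drawn from 2-6 px. Everything is a deterministic function of the seed.
#'
#' @param ds An [dataset_spec()] object.
#' @param class_seed Integer seed for this class.
#' @param class_id Identifier stored in the result.
#' @return A list of class `"fv_class_spec"` with `class_id`, `seed`,
#'   `polylines` (each a list with dense `x`, `y` coordinates and `width`).
#' @export
make_class <- function(ds, class_seed, class_id = "class") {
  set.seed(class_seed)
  h <- ds$height; w <- ds$width
  band <- finger_band_rows(ds)
  n_veins <- sample(3:7, 1L)
  polylines <- vector("list", n_veins)
  for (v in seq_len(n_veins)) {
    n_ctrl <- sample(4:6, 1L)
    cx <- seq(-0.05 * w, 1.05 * w, length.out = n_ctrl)
    y0 <- stats::runif(1, band[1] + 0.15 * diff(band),
                       band[2] - 0.15 * diff(band))
    cy <- y0 + cumsum(stats::rnorm(n_ctrl, 0, 0.08 * diff(band)))
    cy <- pmin(pmax(cy, band[1] + 2), band[2] - 2)
    dense_x <- seq(cx[1], cx[n_ctrl], length.out = 4L * w)
    dense_y <- stats::spline(cx, cy, xout = dense_x)$y
    polylines[[v]] <- list(x = dense_x, y = dense_y,
                           width = stats::runif(1, 2, 6))
  }
  structure(list(class_id = class_id, seed = class_seed,
                 polylines = polylines),
            class = "fv_class_spec")
}

# rows occupied by the bright finger band (about the central 70%)
finger_band_rows <- function(ds) {
  c(round(0.15 * ds$height), round(0.85 * ds$height))
}

#' Render one image instance of a vein class
#'
#' Applies a per-instance rigid perturbation (rotation about the image
#' centre, then shift) to the class skeleton, stamps each vein as a dark
#' valley with a Gaussian cross-profile of its width, adds the finger band,
#' an illumination gradient, blur and noise, and returns both the 8-bit-range
#' image and the ground-truth vein mask (pixels within half a width of a
#' vein centreline).
#'
#' @param cls An [make_class()] specification.
#' @param ds The [dataset_spec()].
#' @param instance_seed Integer seed for this instance's perturbation and
#'   noise.
#' @return A list with `image` (matrix, values in `[0, 255]`), `mask`
#'   (0/1 matrix), `shift` (`c(dy, dx)`), `rotation` (degrees).
#' @export
render_image <- function(cls, ds, instance_seed) {
  set.seed(instance_seed)
  h <- ds$height; w <- ds$width
  rot <- stats::runif(1, -ds$rotation_deg, ds$rotation_deg)
  dy <- stats::runif(1, -ds$shift_px, ds$shift_px)
  dx <- stats::runif(1, -ds$shift_px, ds$shift_px)
  theta <- rot * pi / 180
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2

  drop <- matrix(0, h, w)   # vein intensity drop
  dist2 <- matrix(Inf, h, w)  # squared distance to nearest centreline, scaled
  mask <- matrix(0L, h, w)
  for (pl in cls$polylines) {
    x <- cx0 + cos(theta) * (pl$x - cx0) - sin(theta) * (pl$y - cy0) + dx
    y <- cy0 + sin(theta) * (pl$x - cx0) + cos(theta) * (pl$y - cy0) + dy
    half <- pl$width / 2
    s2 <- (half / 1.177)^2  # Gaussian profile: half-width at half-maximum
    r <- ceiling(3 * half)
    keep <- x > -r & x < w + r & y > -r & y < h + r
    xs <- x[keep]; ys <- y[keep]
    for (i in seq_along(xs)) {
      c0 <- max(1L, floor(xs[i] - r)); c1 <- min(w, ceiling(xs[i] + r))
      r0 <- max(1L, floor(ys[i] - r)); r1 <- min(h, ceiling(ys[i] + r))
      if (c0 > c1 || r0 > r1) next
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - ys[i])^2, (cc - xs[i])^2, `+`)
      g <- ds$contrast * exp(-d2 / (2 * s2))
      drop[rr, cc] <- pmax(drop[rr, cc], g)
      hit <- d2 <= half^2
      if (any(hit)) mask[rr, cc][hit] <- 1L
    }
  }

  band <- finger_band_rows(ds)
  img <- matrix(ds$border, h, w)
  img[band[1]:band[2], ] <- ds$background
  img <- img - drop
  # linear illumination gradient in a random direction
  phi <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(rep(seq_len(w) / w - 0.5, each = h), h, w)
  gy <- matrix(rep(seq_len(h) / h - 0.5, times = w), h, w)
  img <- img + ds$illum_amplitude * (cos(phi) * gx + sin(phi) * gy)
  if (ds$blur_sigma > 0) img <- gaussian_blur(img, ds$blur_sigma)
  if (ds$noise_sd > 0) img <- img + stats::rnorm(h * w, 0, ds$noise_sd)
  img <- pmin(pmax(img, 0), 255)
  # mask outside the finger band is meaningless
  mask[-(band[1]:band[2]), ] <- 0L
  list(image = img, mask = mask, shift = c(dy = dy, dx = dx), rotation = rot)
}

#' Generate and write a synthetic dataset to disk
#'
#' Writes `n_classes x m_images` 8-bit PNG images under
#' `root/<class>/<image>.png`, ground-truth masks under `root/masks/`, and a
#' YAML manifest recording every parameter and derived seed so the dataset
#' can be regenerated byte-for-byte.
#'
#' @param ds An [dataset_spec()].
#' @param root Output directory (created if missing).
#' @return The manifest, invisibly (a list).
#' @export
make_dataset <- function(ds, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), showWarnings = FALSE)
  seeds <- derive_seeds(ds)
  manifest <- list(spec = unclass(ds), classes = list())
  for (g in seq_len(ds$n_classes)) {
    class_id <- sprintf("class_%03d", g)
    cls <- make_class(ds, seeds$class_seeds[g], class_id)
    dir.create(file.path(root, class_id), showWarnings = FALSE)
    images <- list()
    for (j in seq_len(ds$m_images)) {
      iseed <- seeds$instance_seeds[g, j]
      inst <- render_image(cls, ds, iseed)
      img_id <- sprintf("img_%02d", j)
      png::writePNG(inst$image / 255,
                    file.path(root, class_id, paste0(img_id, ".png")))
      png::writePNG(inst$mask + 0,
                    file.path(root, "masks",
                              paste0(class_id, "_", img_id, ".png")))
      images[[img_id]] <- list(seed = iseed)
    }
    manifest$classes[[class_id]] <- list(seed = seeds$class_seeds[g],
                                         images = images)
  }
  yaml::write_yaml(manifest, file.path(root, "manifest.yaml"))
  invisible(manifest)
}

#' Generate a synthetic dataset in memory
#'
#' Like [make_dataset()] but returns the images, masks and class structure
#' as a list without touching the filesystem. Used by the tests and the
#' verification protocol.
#'
#' @param ds An [dataset_spec()].
#' @return Named list of classes; each class is a named list of instances
#'   (`image`, `mask`, `shift`, `rotation`).
#' @export
generate_dataset <- function(ds) {
  seeds <- derive_seeds(ds)
  out <- list()
  for (g in seq_len(ds$n_classes)) {
    class_id <- sprintf("class_%03d", g)
    cls <- make_class(ds, seeds$class_seeds[g], class_id)
    imgs <- list()
    for (j in seq_len(ds$m_images)) {
      imgs[[sprintf("img_%02d", j)]] <-
        render_image(cls, ds, seeds$instance_seeds[g, j])
    }
    out[[class_id]] <- imgs
  }
  out
}

# class and instance seeds as a deterministic function of the master seed,
# kept within 32-bit integer range
derive_seeds <- function(ds) {
  set.seed(ds$seed)
  list(class_seeds = sample.int(.Machine$integer.max, ds$n_classes),
       instance_seeds = matrix(sample.int(.Machine$integer.max,
                                          ds$n_classes * ds$m_images),
                               ds$n_classes, ds$m_images))
}
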