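# Small deterministic images used across the tests.

# column ramp I(x, y) = x / w
ramp_image <- function(h = 24, w = 24) {
  matrix(rep(seq_len(w) / w, each = h), h, w, byrow = FALSE)
}

# paraboloid centred on the image, I = (x^2 + y^2) scaled
paraboloid_image <- function(n = 41, scale = 100) {
  ctr <- (n + 1) / 2
  outer(seq_len(n) - ctr, seq_len(n) - ctr, function(y, x) (x^2 + y^2) / scale)
}

# bright horizontal band (synthetic finger) on a dark background
band_image <- function(h = 160, w = 120, top = 40, bottom = 120,
                       bright = 0.8, dark = 0.1) {
  img <- matrix(dark, h, w)
  img[top:bottom, ] <- bright
  img
}

# straight vertical dark vein with Gaussian cross-profile on a flat field
vein_line_image <- function(h = 40, w = 60, col0 = 30, width = 4,
                            level = 0.7, drop = 0.3) {
  s2 <- (width / 2 / 1.177)^2
  prof <- drop * exp(-((seq_len(w) - col0)^2) / (2 * s2))
  matrix(rep(level - prof, each = h), h, w)
}

random_pattern <- function(h, w, density) {
  matrix(rbinom(h * w, 1L, density), h, w)
}

small_test_dataset <- function(n_classes = 4, m_images = 3, seed = 7) {
  dataset_spec(n_classes = n_classes, m_images = m_images,
               height = 64, width = 96, seed = seed)
}
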