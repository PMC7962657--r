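test_that("gradient field is zero on constant images and unit on ramps", {
  flat <- matrix(0.4, 20, 20)
  gf <- gradient_field(flat, sigma = 2)
  expect_equal(max(abs(gf$gx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gf$gy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gf$ux)), 0, tolerance = 1e-6)
  expect_equal(max(abs(gf$uy)), 0, tolerance = 1e-6)

  gf <- gradient_field(ramp_image(24, 24), sigma = 2)
  interior <- 9:16
  expect_equal(max(abs(gf$ux[interior, interior] - 1)), 0, tolerance = 1e-4)
  expect_equal(max(abs(gf$uy[interior, interior])), 0, tolerance = 1e-8)
  expect_true(all(gf$ux^2 + gf$uy^2 <= 1 + 1e-12))
})

test_that("gradient field rotates with the image", {
  set.seed(11)
  img <- gaussian_blur <- veinrlf:::gaussian_blur(matrix(runif(32 * 32), 32), 2)
  gf <- gradient_field(img, sigma = 1.5)
  rot <- veinrlf:::rotate90k(img, 1)  # counter-clockwise quarter turn
  gfr <- gradient_field(rot, sigma = 1.5)
  # under this quarter turn rot[r', c'] = img[c', W+1-r'], so the column
  # derivative of rot is the row derivative of img and vice versa (negated)
  interior <- 6:27
  expect_equal(gfr$ux[interior, interior],
               veinrlf:::rotate90k(gf$uy, 1)[interior, interior],
               tolerance = 1e-6)
  expect_equal(gfr$uy[interior, interior],
               veinrlf:::rotate90k(-gf$ux, 1)[interior, interior],
               tolerance = 1e-6)
})

test_that("mean curvature is zero on constants and negative in valleys", {
  expect_true(all(mean_curvature(matrix(1, 16, 16))$kappa == 0))

  # straight dark valley I = (x - x0)^2: strongly negative response at x0
  w <- 41; x0 <- 21
  img <- matrix(rep(((seq_len(w) - x0) / w)^2, each = 31), 31, w)
  k <- mean_curvature(img, sigma = 1, epsilon = 1e-9)
  valley <- k$kappa[16, (x0 - 1):(x0 + 1)]
  elsewhere <- abs(k$kappa[16, c(5:(x0 - 6), (x0 + 6):(w - 4))])
  expect_lt(max(valley), 0)
  expect_gt(min(abs(valley)), 10 * max(elsewhere))
})

test_that("paraboloid curvature matches the closed form 1/(2r)", {
  img <- paraboloid_image(41)
  closed <- oracle_mean_curvature_closed(img, sigma = 1)
  ctr <- 21
  # dark centre: closed form at radius 2 is -1/(2*2) = -0.25
  expect_equal(closed[ctr, ctr + 2], -0.25, tolerance = 0.01)
  # divergence form agrees with the 1/(2r) law where the field is resolved
  k <- mean_curvature(img, sigma = 1, epsilon = 1e-9)
  for (r in c(5, 8)) {
    expect_equal(k$kappa[ctr, ctr + r], -1 / (2 * r), tolerance = 0.05)
  }
})

test_that("divergence form tracks the closed form on smooth surfaces", {
  # surfaces whose unit-gradient field is resolved by the pixel grid: the
  # centred paraboloid and a Gaussian blob, away from the critical point
  surfaces <- list(
    paraboloid = paraboloid_image(41),
    blob = outer(seq_len(41), seq_len(41),
                 function(y, x) exp(-((x - 21)^2 + (y - 21)^2) / 200))
  )
  for (nm in names(surfaces)) {
    img <- surfaces[[nm]]
    k <- mean_curvature(img, sigma = 1, epsilon = 1e-9)
    closed <- oracle_mean_curvature_closed(img, sigma = 1)
    gf <- gradient_field(img, sigma = 1, epsilon = 1e-9)
    n <- nrow(img)
    rr <- outer(seq_len(n) - 21, seq_len(n) - 21,
                function(a, b) sqrt(a^2 + b^2))
    sel <- gf$norm > 10 * gf$epsilon & abs(closed) > 1e-3 & rr >= 5
    sel[c(1:7, (n - 6):n), ] <- FALSE
    sel[, c(1:7, (n - 6):n)] <- FALSE
    rel <- abs(k$kappa[sel] - closed[sel]) / abs(closed[sel])
    expect_gt(sum(sel), 500)
    expect_lt(max(rel), 0.05)
  }
})

test_that("curvature is invariant to offsets and contrast scaling", {
  set.seed(5)
  img <- veinrlf:::gaussian_blur(matrix(runif(30 * 30), 30), 2)
  k <- mean_curvature(img, sigma = 1.5, epsilon = 1e-12)
  k_off <- mean_curvature(img + 0.37, sigma = 1.5, epsilon = 1e-12)
  expect_equal(k$kappa, k_off$kappa, tolerance = 1e-9)
  k_scaled <- mean_curvature(3 * img, sigma = 1.5, epsilon = 1e-12)
  gf <- gradient_field(img, sigma = 1.5, epsilon = 1e-12)
  strong <- gf$norm > 1e-3
  expect_equal(k$kappa[strong], k_scaled$kappa[strong], tolerance = 1e-6)
})

test_that("vein response is the negative part of curvature", {
  k <- matrix(c(-0.3, 0.2, 0, -0.01), 2, 2)
  r <- vein_response(k)
  expect_equal(r, matrix(c(0.3, 0, 0, 0.01), 2, 2))
  expect_true(all(vein_response(abs(k)) == 0))
})

test_that("a dark line yields a concentrated positive response", {
  img <- vein_line_image(40, 60, col0 = 30, width = 4)
  resp <- vein_response(mean_curvature(img, sigma = 2))
  inside <- resp[10:30, 29:31]
  background <- resp[10:30, c(5:15, 45:55)]
  expect_gte(min(inside), 5 * max(stats::median(background), 1e-12))
})

test_that("response maps rotate with the image", {
  img <- vein_line_image(32, 48, col0 = 24, width = 4)
  r1 <- vein_response(mean_curvature(img, sigma = 2))
  r2 <- vein_response(mean_curvature(veinrlf:::rotate90k(img, 1), sigma = 2))
  interior <- function(m) m[5:(nrow(m) - 4), 5:(ncol(m) - 4)]
  expect_equal(interior(r2), interior(veinrlf:::rotate90k(r1, 1)),
               tolerance = 1e-8)
})
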