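test_that("PNG images round-trip through load_gray_image", {
  f <- withr::local_tempfile(fileext = ".png")
  px <- matrix(c(0, 255, 128, 64) / 255, 2, 2)
  png::writePNG(px, f)
  img <- load_gray_image(f)
  expect_equal(img, px, tolerance = 1 / 255)

  # RGB with equal channels reads back as that grey level
  frgb <- withr::local_tempfile(fileext = ".png")
  arr <- array(100 / 255, dim = c(3, 4, 3))
  png::writePNG(arr, frgb)
  expect_equal(load_gray_image(frgb),
               matrix(100 / 255, 3, 4), tolerance = 1 / 255)
})

test_that("unreadable and missing files raise errors", {
  expect_error(load_gray_image(file.path(tempdir(), "no-such-file.png")),
               "not found")
  f <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(c(137, 80, 78)), f)  # truncated PNG signature
  expect_error(load_gray_image(f), "unreadable")
})

test_that("8-bit grayscale BMP files are read correctly", {
  # hand-build an 8-bit palettized BMP: 3x2, grayscale palette
  f <- withr::local_tempfile(fileext = ".bmp")
  w <- 3L; h <- 2L
  stride <- 4L  # 3 bytes padded to 4
  pal <- as.raw(t(cbind(0:255, 0:255, 0:255, 0)))
  # rows bottom-up: bottom row (10, 20, 30), top row (200, 150, 100)
  pixdata <- as.raw(c(10, 20, 30, 0, 200, 150, 100, 0))
  data_off <- 14L + 40L + 1024L
  con <- file(f, "wb")
  writeChar("BM", con, eos = NULL)
  writeBin(as.integer(data_off + stride * h), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(data_off, con, size = 4)
  writeBin(40L, con, size = 4)                    # BITMAPINFOHEADER
  writeBin(w, con, size = 4)
  writeBin(h, con, size = 4)
  writeBin(1L, con, size = 2)
  writeBin(8L, con, size = 2)                     # 8 bpp
  writeBin(0L, con, size = 4)                     # BI_RGB
  writeBin(as.integer(stride * h), con, size = 4)
  writeBin(c(2835L, 2835L, 256L, 0L), con, size = 4)
  writeBin(pal, con)
  writeBin(pixdata, con)
  close(con)

  img <- load_gray_image(f)
  expect_equal(dim(img), c(2L, 3L))
  expect_equal(img * 255,
               matrix(c(200, 150, 100, 10, 20, 30), 2, 3, byrow = TRUE))
})

test_that("crop_and_scale with the identity preset is the identity map", {
  set.seed(3)
  img <- matrix(runif(30 * 40), 30, 40)
  expect_identical(crop_and_scale(img, db_preset("none")), img)
})

test_that("crops are applied before scaling and respect bounds", {
  img <- matrix(0, 480, 640)
  p <- db_preset("mmcbnu")
  cropped <- img[(1 + 5):(480 - 5), (1 + 5):(640 - 5)]
  expect_equal(dim(cropped), c(470L, 630L))
  expect_error(
    crop_and_scale(matrix(0, 8, 8),
                   db_preset(crop_top = 5, crop_bottom = 5)),
    "crop exceeds"
  )
})

test_that("the floor(n*s)+1 rule reproduces all four database sizes", {
  raw_sizes <- list(  # post-rotation raster sizes (rows x cols)
    hkpu   = c(256L, 513L),
    mmcbnu = c(480L, 640L),
    fvusm  = c(640L, 480L),
    zscfv  = c(384L, 512L)
  )
  expected <- list(
    hkpu   = c(109L, 217L),
    mmcbnu = c(118L, 158L),
    fvusm  = c(171L, 203L),
    zscfv  = c(173L, 237L)
  )
  for (nm in names(raw_sizes)) {
    p <- db_preset(nm)
    sz <- raw_sizes[[nm]]
    img <- matrix(0, sz[1], sz[2])
    if (p$rotate_deg != 0) img <- matrix(0, sz[2], sz[1])  # pre-rotation
    out <- crop_and_scale(img, p)
    expect_equal(dim(out), expected[[nm]], info = nm)
  }
})

test_that("bicubic resize interpolates smooth ramps accurately", {
  img <- ramp_image(40, 60)
  out <- veinrlf:::resize_bicubic(img, 21, 31)
  # a linear ramp must stay linear under cubic interpolation
  expect_equal(out[11, ], seq(img[1, 1], img[1, 60], length.out = 31),
               tolerance = 1e-10)
})

test_that("locate_roi finds a bright band and is translation-equivariant", {
  img <- band_image(160, 120, top = 40, bottom = 120)
  roi <- locate_roi(img)
  expect_false(roi$fallback)
  truth <- matrix(0L, 160, 120)
  truth[40:120, ] <- 1L
  inter <- sum(roi$mask & truth)
  union <- sum(roi$mask | truth)
  expect_gte(inter / union, 0.8)

  shifted <- band_image(160, 120, top = 50, bottom = 130)
  roi2 <- locate_roi(shifted)
  expect_lte(abs((roi2$bbox[1] - roi$bbox[1]) - 10), 2)
  expect_lte(abs((roi2$bbox[3] - roi$bbox[3]) - 10), 2)
})

test_that("locate_roi falls back to the whole image when featureless", {
  img <- matrix(0.5, 64, 64)
  roi <- locate_roi(img)
  expect_true(roi$fallback)
  expect_equal(roi$bbox, c(1L, 1L, 64L, 64L))
  expect_true(all(roi$mask == 1))
})
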