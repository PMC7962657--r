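#' Load a grayscale image
#'
#' Reads a PNG or BMP file as a single-channel intensity matrix. Multi-channel
#' (colour) inputs are reduced to one channel by the unweighted channel mean:
#' near-infrared captures carry the same signal in every channel, so a
#' luminance weighting would add nothing.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return A numeric matrix (rows x cols) with intensities in `[0, 1]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(c(0, 1, 0.5, 0.25), 2, 2), f)
#' img <- load_gray_image(f)
#' dim(img)
load_gray_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      stop("unreadable image: ", path, " (", conditionMessage(e), ")",
           call. = FALSE)
    }),
    bmp = read_bmp_gray(path),
    stop("unsupported image format: .", ext, " (expected PNG or BMP)",
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    # drop an alpha channel if present, then average the colour channels
    nch <- dim(img)[3]
    if (nch == 4L || nch == 2L) img <- img[, , -nch, drop = FALSE]
    img <- apply(img, c(1, 2), mean)
  }
  img <- as.matrix(img)
  if (nrow(img) < 1L || ncol(img) < 1L || !all(is.finite(img))) {
    stop("unreadable image: ", path, call. = FALSE)
  }
  img
}

#' Write a grayscale image as PNG
#'
#' @param img Numeric matrix. Values outside `[0, 1]` are rescaled to that
#'   range first (min-max); a constant matrix is written as all black.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  }
  png::writePNG(img, path)
  invisible(path)
}

# Minimal BMP reader: uncompressed 8-bit palettized and 24/32-bit BI_RGB files,
# the variants vein databases ship ("8-bit bitmap format with 256 grayscale
# levels"). Rows are stored bottom-up and padded to 4-byte boundaries.
read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM") {
    stop("unreadable image: ", path, " (not a BMP file)", call. = FALSE)
  }
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10L)
  hdr_size <- u32(14L)
  w <- u32(18L)
  h_raw <- u32(22L)
  # height may be negative (top-down); stored as two's complement
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- u16(28L)
  compression <- u32(30L)
  if (compression != 0L) {
    stop("unreadable image: ", path, " (compressed BMP not supported)",
         call. = FALSE)
  }
  if (!bpp %in% c(8L, 24L, 32L)) {
    stop("unreadable image: ", path, " (unsupported bit depth ", bpp, ")",
         call. = FALSE)
  }
  if (w < 1L || h < 1L) stop("unreadable image: ", path, call. = FALSE)

  if (bpp == 8L) {
    n_pal <- u32(46L)
    if (n_pal == 0L) n_pal <- 256L
    pal_off <- 14L + hdr_size
    pal <- matrix(as.integer(raw[pal_off + seq_len(4L * n_pal)]),
                  ncol = 4L, byrow = TRUE)  # B, G, R, reserved
    gray_lut <- rowMeans(pal[, 1:3, drop = FALSE]) / 255
    stride <- 4L * ceiling(w / 4)
    need <- data_off + stride * h
    if (length(raw) < need) stop("unreadable image: ", path, call. = FALSE)
    px <- matrix(as.integer(raw[data_off + seq_len(stride * h)]),
                 nrow = stride)[seq_len(w), , drop = FALSE]
    img <- t(matrix(gray_lut[px + 1L], nrow = w))
  } else {
    bytespp <- bpp %/% 8L
    stride <- 4L * ceiling(w * bytespp / 4)
    need <- data_off + stride * h
    if (length(raw) < need) stop("unreadable image: ", path, call. = FALSE)
    rows <- matrix(as.integer(raw[data_off + seq_len(stride * h)]),
                   nrow = stride)
    img <- matrix(0, nrow = h, ncol = w)
    for (ch in 1:3) {  # B, G, R
      idx <- (seq_len(w) - 1L) * bytespp + ch
      img <- img + t(rows[idx, , drop = FALSE]) / 255
    }
    img <- img / 3
  }
  if (!top_down) img <- img[h:1, , drop = FALSE]
  img
}
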