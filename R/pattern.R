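#' Min-max normalization to [0, 1]
#'
#' Affine rescale of a raster so its minimum maps to 0 and maximum to 1. A
#' constant raster carries no vein information and maps to all zeros.
#'
#' @param raster Numeric matrix with finite values.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_minmax <- function(raster) {
  stopifnot(is.matrix(raster), all(is.finite(raster)))
  rng <- range(raster)
  if (rng[1] == rng[2]) {
    return(matrix(0, nrow(raster), ncol(raster)))
  }
  (raster - rng[1]) / (rng[2] - rng[1])
}

#' Otsu threshold of a normalized raster
#'
#' Threshold maximizing the between-class variance of a 256-bin histogram of
#' values in `[0, 1]`. Delegates to `EBImage::otsu()`.
#'
#' @param raster Numeric matrix with values in `[0, 1]` and at least two
#'   distinct values.
#' @return Threshold scalar in `(0, 1)`.
#' @export
otsu_threshold <- function(raster) {
  stopifnot(is.matrix(raster), all(is.finite(raster)))
  if (min(raster) < 0 || max(raster) > 1) {
    stop("`raster` must be normalized to [0, 1]; see normalize_minmax()",
         call. = FALSE)
  }
  if (length(unique(as.vector(raster))) < 2L) {
    stop("degenerate histogram: raster is constant", call. = FALSE)
  }
  as.numeric(EBImage::otsu(raster, range = c(0, 1), levels = 256))
}

#' Binarize a raster into a vein pattern
#'
#' Pixels strictly above the threshold become vein (1); ties go to background,
#' which keeps the rule deterministic. Veins are high-response after the
#' curvature/RLF stages, so 1 marks vein.
#'
#' @param raster Numeric matrix in `[0, 1]`.
#' @param thr Threshold in `[0, 1]`.
#' @return An integer 0/1 matrix of class `"fv_pattern"` with attribute
#'   `vein_count` (number of 1 pixels).
#' @export
#' @examples
#' binarize(matrix(c(0, 0.5, 1), 1), 0.5)
binarize <- function(raster, thr) {
  stopifnot(is.matrix(raster), is.numeric(thr), length(thr) == 1L,
            thr >= 0, thr <= 1)
  px <- matrix(as.integer(raster > thr), nrow(raster), ncol(raster))
  structure(px, class = c("fv_pattern", class(px)),
            vein_count = sum(px))
}

#' Normalize and binarize a feature raster in one step
#'
#' Convenience wrapper: min-max normalization followed by Otsu thresholding
#' and binarization. This is the final stage of both the RLF pipeline (on the
#' mean RLF image) and the mean-curvature baseline (directly on the valley
#' response).
#'
#' @param raster Numeric matrix (any finite range).
#' @return An `"fv_pattern"` 0/1 matrix.
#' @export
vein_pattern <- function(raster) {
  norm <- normalize_minmax(raster)
  if (all(norm == 0)) {
    # structureless response: no veins rather than a degenerate Otsu error
    return(binarize(norm, 1))
  }
  binarize(norm, otsu_threshold(norm))
}
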