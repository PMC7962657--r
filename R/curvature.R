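#' Regularized image gradient field
#'
#' Estimates the first partial derivatives of an intensity image by
#' derivative-of-Gaussian filtering at scale `sigma`, together with the
#' gradient magnitude and the epsilon-regularized unit gradient field
#' `u = grad(I) / (|grad(I)| + epsilon)`. The unit field is the quantity whose
#' divergence gives the mean curvature; the regularizer keeps it defined (and
#' zero) in flat regions.
#'
#' The x axis runs along columns and the y axis along rows, so `gx` is the
#' column-wise and `gy` the row-wise derivative.
#'
#' @param img Numeric intensity matrix.
#' @param sigma Gaussian derivative scale in pixels (> 0). Default 2: vein
#'   cross-sections in scaled finger images are a few pixels wide and the raw
#'   captures are noisy, so derivative estimates need comparable smoothing.
#' @param epsilon Gradient regularizer. `NULL` (default) uses
#'   `1e-6 * max(|grad(I)|)`, which scales with image contrast.
#' @return A list of class `"fv_gradient"` with matrices `gx`, `gy`, `norm`,
#'   `ux`, `uy` and the scalars `sigma`, `epsilon`.
#' @export
gradient_field <- function(img, sigma = 2, epsilon = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar", call. = FALSE)
  }
  g <- gaussian_kernel(sigma)
  d <- gaussian_deriv_kernel(sigma)
  gx <- filter_sep(img, d, g)
  gy <- filter_sep(img, g, d)
  # clip numerical noise so flat images have an exactly zero field
  noise_floor <- 1e-10 * max(abs(img), 1)
  gx[abs(gx) < noise_floor] <- 0
  gy[abs(gy) < noise_floor] <- 0
  nrm <- sqrt(gx^2 + gy^2)
  if (is.null(epsilon)) epsilon <- 1e-6 * max(nrm)
  if (epsilon <= 0) epsilon <- .Machine$double.eps
  structure(
    list(gx = gx, gy = gy, norm = nrm,
         ux = gx / (nrm + epsilon), uy = gy / (nrm + epsilon),
         sigma = sigma, epsilon = epsilon),
    class = "fv_gradient"
  )
}

#' Mean curvature of the intensity surface
#'
#' Computes the mean-curvature field `kappa = -1/2 div(u)` where `u` is the
#' epsilon-regularized unit gradient of the image. Dark curvilinear valleys
#' (veins in NIR finger images) have negative curvature under this sign
#' convention; bright ridges are positive. The divergence is taken by central
#' differences of the unit field with replicate borders.
#'
#' @inheritParams gradient_field
#' @return A list of class `"fv_curvature"` with the matrix `kappa` and the
#'   scalars `sigma`, `epsilon`.
#' @seealso [vein_response()] for the non-negative valley response.
#' @export
#' @examples
#' img <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
#'              function(y, x) (x - 0.5)^2)
#' k <- mean_curvature(img)
#' range(k$kappa)
mean_curvature <- function(img, sigma = 2, epsilon = NULL) {
  gf <- gradient_field(img, sigma = sigma, epsilon = epsilon)
  kappa <- -0.5 * (central_diff(gf$ux, 2L) + central_diff(gf$uy, 1L))
  structure(list(kappa = kappa, sigma = gf$sigma, epsilon = gf$epsilon),
            class = "fv_curvature")
}

#' Valley response from a mean-curvature field
#'
#' The vein (valley) response is the negative part of the mean curvature,
#' `max(-kappa, 0)`: dark valleys map to positive response, bright ridges and
#' flat regions to zero. This is the raster the Radon-like features aggregate.
#'
#' @param curv An `"fv_curvature"` object from [mean_curvature()], or a bare
#'   curvature matrix.
#' @return A numeric matrix of non-negative responses.
#' @export
vein_response <- function(curv) {
  kappa <- if (inherits(curv, "fv_curvature")) curv$kappa else curv
  stopifnot(is.matrix(kappa))
  pmax(-kappa, 0)
}
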