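#' Matching configuration
#'
#' Margins cut from the registered image to form the template sub-image. The
#' probe may then shift by up to `2*ch` rows and `2*cw` columns relative to
#' the template, which is what makes the matcher tolerant to finger
#' displacement between captures.
#'
#' @param cw,ch Horizontal / vertical margin in pixels (defaults 30, the
#'   margin setting the method performs best with on full finger regions).
#' @return A list of class `"fv_match_config"`.
#' @export
match_config <- function(cw = 30L, ch = 30L) {
  stopifnot(is.numeric(cw), is.numeric(ch), length(cw) == 1L,
            length(ch) == 1L, cw >= 0, ch >= 0)
  structure(list(cw = as.integer(cw), ch = as.integer(ch)),
            class = "fv_match_config")
}

#' Crop the matching template from a registered pattern
#'
#' Removes `ch` rows top and bottom and `cw` columns left and right, leaving
#' the central `(H - 2*ch) x (W - 2*cw)` sub-image.
#'
#' @param registered 0/1 binary pattern matrix.
#' @param cfg An [match_config()] object (or list with `cw`, `ch`).
#' @return The cropped 0/1 matrix.
#' @export
crop_template <- function(registered, cfg = match_config()) {
  stopifnot(is.matrix(registered))
  h <- nrow(registered); w <- ncol(registered)
  if (2L * cfg$ch >= h || 2L * cfg$cw >= w) {
    stop("margins too large: need 2*ch < H and 2*cw < W", call. = FALSE)
  }
  registered[(cfg$ch + 1L):(h - cfg$ch), (cfg$cw + 1L):(w - cfg$cw),
             drop = FALSE]
}

#' Match ratio between a registered and a probe vein pattern
#'
#' Crops the template from the registered pattern, slides it over the probe
#' across every allowed offset `(dy, dx)` in `[0, 2*ch] x [0, 2*cw]`, and
#' returns the maximal match ratio
#' `Rm = Ncommon / (Ntemplate + Ninput)`,
#' where `Ncommon` counts co-located vein pixels, and `Ntemplate` / `Ninput`
#' count the vein pixels of the template and of the covered probe window.
#' `Rm = 0.5` for an exact match, 0 when the vein sets never overlap, and
#' 0 by convention when both windows are empty. Ties between offsets are
#' broken by the smallest `(dy, dx)` in row-major order.
#'
#' The offset search is exhaustive but computed for all offsets at once:
#' `Ncommon` via an FFT cross-correlation and `Ninput` via an integral image,
#' so the result is identical to an explicit sliding-window loop.
#'
#' @param registered,probe 0/1 binary pattern matrices of the same shape.
#' @param cfg An [match_config()] object.
#' @return A list of class `"fv_match"` with `rm`, `offset` (`c(dy, dx)`,
#'   0-based displacement), `n_common`, `n_template`, `n_input`.
#' @export
#' @examples
#' set.seed(1)
#' p <- matrix(rbinom(100, 1, 0.3), 10, 10)
#' match_ratio(p, p, match_config(cw = 0, ch = 0))$rm  # exact match: 0.5
match_ratio <- function(registered, probe, cfg = match_config()) {
  stopifnot(is.matrix(registered), is.matrix(probe))
  if (!all(dim(registered) == dim(probe))) {
    stop("`registered` and `probe` must have the same shape", call. = FALSE)
  }
  h <- nrow(probe); w <- ncol(probe)
  tmpl <- crop_template(registered, cfg)
  th <- nrow(tmpl); tw <- ncol(tmpl)
  n_template <- sum(tmpl)
  n_dy <- h - th + 1L  # = 2*ch + 1
  n_dx <- w - tw + 1L  # = 2*cw + 1

  # Ncommon at every offset: circular cross-correlation; the template is
  # zero-padded to the probe size, so offsets up to (2ch, 2cw) never wrap.
  tp <- matrix(0, h, w)
  tp[seq_len(th), seq_len(tw)] <- tmpl
  cc <- Re(stats::fft(stats::fft(probe + 0) * Conj(stats::fft(tp)),
                      inverse = TRUE)) / (h * w)
  n_common <- round(cc[seq_len(n_dy), seq_len(n_dx), drop = FALSE])

  # Ninput at every offset: window sums of the probe via an integral image
  ii <- rbind(0, cbind(0, apply(apply(probe, 2L, cumsum), 1L, cumsum)))
  # after the double apply/cbind the matrix is (w+1) x (h+1), transposed
  ii <- t(ii)
  win_sum <- ii[(th + 1L):(h + 1L), (tw + 1L):(w + 1L), drop = FALSE] -
    ii[(th + 1L):(h + 1L), 1L:(w - tw + 1L), drop = FALSE] -
    ii[1L:(h - th + 1L), (tw + 1L):(w + 1L), drop = FALSE] +
    ii[1L:(h - th + 1L), 1L:(w - tw + 1L), drop = FALSE]
  n_input <- win_sum

  denom <- n_template + n_input
  rm_all <- ifelse(denom > 0, n_common / denom, 0)

  best <- max(rm_all)
  # row-major (dy outer, dx inner) tie-break on the smallest offset
  hits <- which(rm_all == best, arr.ind = TRUE)
  ord <- order(hits[, 1L], hits[, 2L])[1L]
  dy <- hits[ord, 1L] - 1L
  dx <- hits[ord, 2L] - 1L

  structure(
    list(rm = best, offset = c(dy = dy, dx = dx),
         n_common = n_common[dy + 1L, dx + 1L],
         n_template = n_template,
         n_input = n_input[dy + 1L, dx + 1L]),
    class = "fv_match"
  )
}
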