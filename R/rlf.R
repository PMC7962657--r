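#' @title Radon-like feature aggregation along scan lines
#' @description
#' Radon-like features (RLF) aggregate a response image along families of
#' digital scan lines. Each line is cut into segments at "knots" — the points
#' where it crosses a Canny edge map — and every pixel of a segment receives
#' the segment's extraction-function value. With the path-integral extraction
#' function used here that value is the arithmetic mean of the response over
#' the segment's pixels, so features stay inside the response's value range
#' and a constant field is reproduced exactly. Averaging the per-direction
#' rasters over the eight 45-degree-spaced directions yields the mean RLF
#' image, a smoother and more connected version of the vein response.
#' @name rlf
NULL

rlf_thetas <- function() c(0L, 45L, 90L, 135L, 180L, 225L, 270L, 315L)

#' Generate the scan-line family for one direction
#'
#' Produces the rasterized digital lines at direction `theta` whose union
#' covers every pixel of an `H x W` raster exactly once: rows for 0/180
#' degrees, columns for 90/270, diagonals and anti-diagonals for the four
#' oblique directions. Traversal order follows the direction (x along
#' columns, y upwards along decreasing rows).
#'
#' @param shape Integer vector `c(H, W)`.
#' @param theta Direction in degrees; one of 0, 45, ..., 315.
#' @return A list of scan lines, each a list with `theta`, `rows`, `cols`,
#'   `idx` (column-major linear indices) and `knots` (`NULL` until
#'   [find_knots()] is applied).
#' @export
#' @examples
#' fam <- generate_scan_lines(c(3, 3), 45)
#' lengths(lapply(fam, `[[`, "idx"))
generate_scan_lines <- function(shape, theta) {
  stopifnot(length(shape) == 2L, shape >= 1L)
  if (!theta %in% rlf_thetas()) {
    stop("unsupported scan-line direction: ", theta,
         " (must be a multiple of 45 in [0, 315])", call. = FALSE)
  }
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  base <- switch(as.character(theta %% 180L),
    "0" = lapply(seq_len(h), function(r) {
      cs <- seq_len(w)
      list(rows = rep.int(r, w), cols = cs)
    }),
    "90" = lapply(seq_len(w), function(c) {
      rs <- seq.int(h, 1L)  # upwards
      list(rows = rs, cols = rep.int(c, h))
    }),
    "45" = lapply(2L:(h + w), function(s) {
      # anti-diagonal r + c = s, traversed up-right (r decreasing)
      rs <- seq.int(min(h, s - 1L), max(1L, s - w))
      list(rows = rs, cols = s - rs)
    }),
    "135" = lapply((1L - h):(w - 1L), function(d) {
      # diagonal c - r = d, traversed up-left (r and c decreasing)
      rs <- seq.int(min(h, w - d), max(1L, 1L - d))
      list(rows = rs, cols = rs + d)
    })
  )
  if (theta >= 180L) {
    base <- lapply(base, function(l) list(rows = rev(l$rows),
                                          cols = rev(l$cols)))
  }
  lapply(base, function(l) {
    list(theta = theta, rows = l$rows, cols = l$cols,
         idx = (l$cols - 1L) * h + l$rows, knots = NULL)
  })
}

#' Locate the knots of a scan line
#'
#' Knots are the positions (1-based indices along the line) where the line
#' crosses the edge map; both endpoints are always knots.
#'
#' @param line A scan line from [generate_scan_lines()].
#' @param edges 0/1 edge matrix covering the line's pixels.
#' @return The line with its `knots` field filled in (strictly increasing,
#'   starting at 1 and ending at the line length).
#' @export
find_knots <- function(line, edges) {
  stopifnot(is.matrix(edges))
  n <- length(line$idx)
  hits <- which(edges[line$idx] != 0)
  line$knots <- unique(c(1L, hits, n))
  line
}

#' Segment-mean extraction along one scan line
#'
#' Splits the line into segments at its knots and assigns every pixel of a
#' segment the arithmetic mean of the response over that segment's pixels
#' (the discrete path integral divided by the segment length). Segments are
#' the half-open knot-to-knot spans; the final pixel belongs to the last
#' segment, so the spans partition the line.
#'
#' @param line A scan line with knots (see [find_knots()]).
#' @param response Numeric response matrix.
#' @return Numeric vector of per-pixel feature values along the line.
#' @export
extract_segments <- function(line, response) {
  stopifnot(is.matrix(response))
  n <- length(line$idx)
  knots <- line$knots
  if (is.null(knots)) knots <- c(1L, n)
  vals <- response[line$idx]
  if (n == 1L || length(knots) <= 2L) {
    return(rep.int(mean(vals), n))
  }
  starts <- knots[-length(knots)]
  ends <- c(knots[-c(1L, length(knots))] - 1L, n)
  cs <- c(0, cumsum(vals))
  seg_sum <- cs[ends + 1L] - cs[starts]
  seg_len <- ends - starts + 1L
  rep.int(seg_sum / seg_len, seg_len)
}

#' Radon-like feature raster for one direction
#'
#' Applies [extract_segments()] over the full scan-line family at direction
#' `theta`; because the family tiles the raster, every pixel is written
#' exactly once and the result is piecewise constant between knots along
#' each line.
#'
#' @param response Numeric response matrix.
#' @param edges 0/1 edge matrix of the same shape.
#' @param theta Direction in degrees (multiple of 45 in `[0, 315]`).
#' @return Numeric matrix of the same shape.
#' @export
rlf_direction <- function(response, edges, theta) {
  stopifnot(is.matrix(response), is.matrix(edges))
  if (!all(dim(response) == dim(edges))) {
    stop("`response` and `edges` must have the same shape", call. = FALSE)
  }
  if (!theta %in% rlf_thetas()) {
    stop("unsupported scan-line direction: ", theta, call. = FALSE)
  }
  # segment means do not depend on traversal direction, but knot-pixel
  # ownership under the half-open span rule would; computing opposite
  # orientations through their canonical direction keeps the identity
  # raster(theta) == raster(theta + 180) exact
  theta <- theta %% 180L
  out <- matrix(NA_real_, nrow(response), ncol(response))
  for (line in generate_scan_lines(dim(response), theta)) {
    line <- find_knots(line, edges)
    out[line$idx] <- extract_segments(line, response)
  }
  out
}

#' Radon-like feature stack and mean RLF image
#'
#' Computes the per-direction RLF rasters for each requested direction plus
#' their pixel-wise mean (the mean RLF image used for binarization and
#' matching). Opposite directions traverse the same lines in reverse and give
#' identical rasters; all eight are still computed so the stack mirrors the
#' eight scan-line groups of the method.
#'
#' @inheritParams rlf_direction
#' @param thetas Integer vector of directions (default all eight).
#' @return A list of class `"fv_rlf"` with `per_direction` (named list of
#'   matrices) and `mean` (matrix).
#' @export
rlf_stack <- function(response, edges, thetas = rlf_thetas()) {
  if (length(thetas) == 0L) stop("`thetas` must be non-empty", call. = FALSE)
  per <- lapply(thetas, function(th) rlf_direction(response, edges, th))
  names(per) <- as.character(thetas)
  structure(list(per_direction = per,
                 mean = Reduce(`+`, per) / length(per)),
            class = "fv_rlf")
}
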