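# Independent brute-force oracles. These deliberately re-derive each result
# with explicit loops and closed forms, sharing no code path with the package
# internals they check.

# exhaustive sliding-window match ratio
oracle_match_ratio <- function(registered, probe, cw, ch) {
  h <- nrow(registered); w <- ncol(registered)
  tmpl <- registered[(ch + 1):(h - ch), (cw + 1):(w - cw), drop = FALSE]
  th <- nrow(tmpl); tw <- ncol(tmpl)
  n_template <- sum(tmpl)
  best <- -1; best_off <- c(NA, NA)
  for (dy in 0:(2 * ch)) {
    for (dx in 0:(2 * cw)) {
      win <- probe[(dy + 1):(dy + th), (dx + 1):(dx + tw), drop = FALSE]
      n_common <- sum(tmpl == 1 & win == 1)
      denom <- n_template + sum(win)
      rm <- if (denom > 0) n_common / denom else 0
      if (rm > best) {
        best <- rm
        best_off <- c(dy, dx)
      }
    }
  }
  list(rm = best, offset = best_off)
}

# per-segment RLF for a single direction, explicit loops; shares the
# documented convention that opposite orientations are computed through the
# canonical direction (knot-pixel ownership is traversal-dependent otherwise)
oracle_rlf_direction <- function(response, edges, theta) {
  out <- matrix(NA_real_, nrow(response), ncol(response))
  for (line in generate_scan_lines(dim(response), theta %% 180)) {
    n <- length(line$idx)
    on_edge <- which(edges[line$idx] != 0)
    knots <- sort(unique(c(1L, on_edge, n)))
    if (n == 1L || length(knots) == 2L) {
      out[line$idx] <- mean(response[line$idx])
      next
    }
    for (i in seq_len(length(knots) - 1L)) {
      from <- knots[i]
      to <- if (i == length(knots) - 1L) knots[i + 1L] else knots[i + 1L] - 1L
      seg <- line$idx[from:to]
      out[seg] <- mean(response[seg])
    }
  }
  out
}

# closed-form mean curvature from Gaussian-derivative partials
oracle_mean_curvature_closed <- function(img, sigma) {
  g <- veinrlf:::gaussian_kernel(sigma)
  d <- veinrlf:::gaussian_deriv_kernel(sigma)
  fs <- veinrlf:::filter_sep
  ix <- fs(img, d, g); iy <- fs(img, g, d)
  ixx <- fs(ix, d, g); iyy <- fs(iy, g, d); ixy <- fs(ix, g, d)
  num <- ixx * iy^2 - 2 * ixy * ix * iy + iyy * ix^2
  den <- (ix^2 + iy^2)^1.5
  -0.5 * num / den
}

# exhaustive 256-bin Otsu search maximizing between-class variance
oracle_otsu <- function(x) {
  breaks <- seq(0, 1, length.out = 257)
  counts <- tabulate(pmin(pmax(findInterval(x, breaks,
                                            rightmost.closed = TRUE), 1),
                          256), nbins = 256)
  mids <- (breaks[-257] + breaks[-1]) / 2
  n <- sum(counts)
  v <- rep(NA_real_, 255)
  for (k in 1:255) {
    w0 <- sum(counts[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  # several cut points can attain the maximum (empty bins between modes);
  # return the variance profile so callers can check attainment
  list(threshold = breaks[which.max(v) + 1], variance = v, breaks = breaks)
}

# FAR/FRR sweep by direct counting at every threshold
oracle_eer <- function(genuine, impostor, step = 1e-4) {
  thresholds <- seq(0, 0.5, by = step)
  far <- vapply(thresholds,
                function(t) 100 * sum(impostor >= t) / length(impostor),
                numeric(1))
  frr <- vapply(thresholds,
                function(t) 100 * sum(genuine < t) / length(genuine),
                numeric(1))
  i <- which.min(abs(far - frr))
  list(eer = (far[i] + frr[i]) / 2, threshold = thresholds[i],
       far = far, frr = frr)
}

# directed Hausdorff distance between the 1-pixel sets of two binary masks
hausdorff_px <- function(a, b) {
  pa <- which(a != 0, arr.ind = TRUE)
  pb <- which(b != 0, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  max(sqrt(pmin.int(apply(d2, 1, min), Inf)),
      sqrt(pmin.int(apply(d2, 2, min), Inf)))
}
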