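#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the FAR/FRR threshold sweep of an EER result
#'
#' @param x An `"fv_eer"` object from [eer()] or [run_verification()].
#' @param ... Unused.
#' @return A tibble with one row per threshold: `threshold`, `far`, `frr`.
#' @method tidy fv_eer
#' @export
tidy.fv_eer <- function(x, ...) {
  x$curve
}

#' One-row summary of an EER result
#'
#' @inheritParams tidy.fv_eer
#' @return A tibble with `eer`, `threshold`, `n_genuine`, `n_impostor`.
#' @method glance fv_eer
#' @export
glance.fv_eer <- function(x, ...) {
  tibble::tibble(eer = x$eer, threshold = x$threshold,
                 n_genuine = x$n_genuine, n_impostor = x$n_impostor)
}

#' One-row summary of a single match attempt
#'
#' @param x An `"fv_match"` object from [match_ratio()].
#' @param ... Unused.
#' @return A tibble with `rm`, `offset_dy`, `offset_dx`, `n_common`,
#'   `n_template`, `n_input`.
#' @method tidy fv_match
#' @export
tidy.fv_match <- function(x, ...) {
  tibble::tibble(rm = x$rm,
                 offset_dy = unname(x$offset[1]),
                 offset_dx = unname(x$offset[2]),
                 n_common = x$n_common,
                 n_template = x$n_template,
                 n_input = x$n_input)
}

#' Plot the FAR/FRR curves of an EER result
#'
#' Draws both error rates against the acceptance threshold with the EER
#' operating point marked.
#'
#' @param object An `"fv_eer"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fv_eer
#' @export
autoplot.fv_eer <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("far", "frr"),
                              names_to = "rate", values_to = "percent")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$threshold, y = .data$percent,
                               colour = toupper(.data$rate))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::annotate("point", x = object$threshold, y = object$eer) +
    ggplot2::labs(x = "acceptance threshold (match ratio)", y = "rate (%)",
                  colour = NULL,
                  title = sprintf("EER = %.2f%% at threshold %.4f",
                                  object$eer, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot an intensity or feature raster
#'
#' Convenience raster display for images, responses, RLF maps and binary
#' patterns, with the row axis flipped so row 1 is at the top.
#'
#' @param img Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_raster <- function(img, title = NULL) {
  stopifnot(is.matrix(img))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
print.fv_eer <- function(x, ...) {
  cat(sprintf(
    "Verification result: EER %.3f%% at threshold %.4f (%d genuine, %d impostor attempts)\n",
    x$eer, x$threshold, x$n_genuine, x$n_impostor))
  invisible(x)
}

#' @export
print.fv_match <- function(x, ...) {
  cat(sprintf(
    "Match ratio %.4f at offset (dy = %d, dx = %d); common %d, template %d, input %d\n",
    x$rm, x$offset[1], x$offset[2], x$n_common, x$n_template, x$n_input))
  invisible(x)
}
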