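#' Build a genuine/impostor score table
#'
#' Runs the verification protocol over a class-labelled set of binary vein
#' patterns: within each class the lexicographically first image is enrolled
#' as the registered template; every other image of the same class then
#' contributes one genuine attempt against it, and every image of every other
#' class contributes one impostor attempt. Classes with fewer than two images
#' are skipped with a warning.
#'
#' @param patterns Named list of classes, each a named list of 0/1 pattern
#'   matrices (names are image ids). Typically produced by
#'   [extract_dataset_patterns()].
#' @param cfg A [match_config()] object.
#' @return A tibble of class `"fv_scores"` with columns `probe_id`,
#'   `gallery_class`, `rm`, `is_genuine`, and attributes `n_genuine`
#'   (NGRA) and `n_impostor` (NIRA).
#' @export
build_score_table <- function(patterns, cfg = match_config()) {
  stopifnot(is.list(patterns))
  if (length(patterns) < 2L) {
    stop("need at least 2 classes for a genuine/impostor protocol",
         call. = FALSE)
  }
  keep <- vapply(patterns, function(cl) length(cl) >= 2L, logical(1))
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " class(es) with fewer than 2 images",
            call. = FALSE)
    patterns <- patterns[keep]
  }
  if (length(patterns) < 2L) {
    stop("fewer than 2 usable classes after skipping", call. = FALSE)
  }
  classes <- names(patterns)
  if (is.null(classes)) classes <- as.character(seq_along(patterns))

  rows <- list()
  for (g in seq_along(patterns)) {
    cls <- patterns[[g]]
    ids <- names(cls)
    if (is.null(ids)) ids <- as.character(seq_along(cls))
    ord <- order(ids)
    template <- cls[[ord[1L]]]
    for (p in seq_along(patterns)) {
      probe_cls <- patterns[[p]]
      probe_ids <- names(probe_cls)
      if (is.null(probe_ids)) probe_ids <- as.character(seq_along(probe_cls))
      for (j in seq_along(probe_cls)) {
        genuine <- p == g
        if (genuine && probe_ids[j] == ids[ord[1L]]) next  # the template itself
        res <- match_ratio(template, probe_cls[[j]], cfg)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          probe_id = paste(classes[p], probe_ids[j], sep = "/"),
          gallery_class = classes[g],
          rm = res$rm,
          is_genuine = genuine
        )
      }
    }
  }
  tbl <- dplyr::bind_rows(rows)
  structure(tbl,
            class = c("fv_scores", class(tbl)),
            n_genuine = sum(tbl$is_genuine),
            n_impostor = sum(!tbl$is_genuine))
}

#' False acceptance and false rejection rates at a threshold
#'
#' An attempt is accepted when its match ratio is at least `t`. FAR is the
#' percentage of impostor attempts accepted; FRR the percentage of genuine
#' attempts rejected.
#'
#' @param table An `"fv_scores"` table (or any data frame with `rm` and
#'   `is_genuine` columns).
#' @param t Threshold in `[0, 0.5]`.
#' @return Named numeric vector `c(far = ..., frr = ...)`, both in percent.
#' @export
far_frr <- function(table, t) {
  stopifnot(is.data.frame(table), all(c("rm", "is_genuine") %in% names(table)))
  gen <- table$rm[table$is_genuine]
  imp <- table$rm[!table$is_genuine]
  if (length(gen) == 0L || length(imp) == 0L) {
    stop("score table must contain both genuine and impostor attempts",
         call. = FALSE)
  }
  c(far = 100 * sum(imp >= t) / length(imp),
    frr = 100 * sum(gen < t) / length(gen))
}

#' Approximate equal error rate over a threshold sweep
#'
#' Sweeps the acceptance threshold over the grid `{0, step, ..., 0.5}` (5001
#' values at the default step of 1e-4), computes FAR and FRR at each value,
#' and reports the EER as `(FAR + FRR) / 2` at the grid point where
#' `|FAR - FRR|` is smallest, ties broken by the smallest threshold.
#'
#' @inheritParams far_frr
#' @param step Threshold grid step (default 1e-4).
#' @return A list of class `"fv_eer"` with `eer` (percent), `threshold`,
#'   `curve` (tibble: `threshold`, `far`, `frr`), `n_genuine`, `n_impostor`.
#' @export
eer <- function(table, step = 1e-4) {
  stopifnot(is.data.frame(table), step > 0, step <= 0.5)
  gen <- sort(table$rm[table$is_genuine])
  imp <- sort(table$rm[!table$is_genuine])
  if (length(gen) == 0L || length(imp) == 0L) {
    stop("score table must contain both genuine and impostor attempts",
         call. = FALSE)
  }
  thresholds <- seq(0, 0.5, by = step)
  # findInterval(t, v, left.open = TRUE) counts elements of v strictly below
  # t, so these match the accept-iff-rm >= t rule of far_frr() exactly
  far <- 100 * (length(imp) -
                  findInterval(thresholds, imp, left.open = TRUE)) /
    length(imp)
  frr <- 100 * findInterval(thresholds, gen, left.open = TRUE) / length(gen)
  gap <- abs(far - frr)
  i <- which.min(gap)  # which.min takes the first minimum: smallest threshold
  structure(
    list(eer = (far[i] + frr[i]) / 2,
         threshold = thresholds[i],
         curve = tibble::tibble(threshold = thresholds, far = far, frr = frr),
         n_genuine = length(gen),
         n_impostor = length(imp)),
    class = "fv_eer"
  )
}

#' Write an EER report to JSON (and optionally the sweep to CSV)
#'
#' @param result An `"fv_eer"` object.
#' @param path Output JSON path.
#' @param curve_path Optional CSV path for the per-threshold FAR/FRR curve.
#' @param settings Optional list of pipeline settings to embed in the report.
#' @return `path`, invisibly.
#' @export
write_eer_report <- function(result, path, curve_path = NULL,
                             settings = NULL) {
  stopifnot(inherits(result, "fv_eer"))
  report <- list(eer_percent = result$eer, threshold = result$threshold,
                 n_genuine = result$n_genuine,
                 n_impostor = result$n_impostor)
  if (!is.null(settings)) report$settings <- settings
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(curve_path)) {
    utils::write.csv(result$curve, curve_path, row.names = FALSE)
  }
  invisible(path)
}
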