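#' Pipeline configuration
#'
#' Collects every tunable parameter of the extraction/matching/evaluation
#' chain with method-faithful defaults: Gaussian-derivative scale 2 px for
#' the curvature, Canny at sigma 1.5 with hysteresis at the 0.7/0.9
#' quantiles, all eight 45-degree scan-line directions, matching margins
#' `cw = ch = 30`, and an EER threshold step of 1e-4.
#'
#' @param preset Database preparation preset name (see [db_preset()]).
#' @param method `"rlf"` (curvature response aggregated by Radon-like
#'   features) or `"mean_curvature"` (binarize the valley response directly;
#'   the comparison baseline).
#' @param curvature_sigma,curvature_epsilon See [mean_curvature()].
#' @param canny_sigma,canny_low,canny_high See [edge_map()].
#' @param thetas Scan-line directions (multiples of 45 in `[0, 315]`).
#' @param cw,ch Matching margins, see [match_config()].
#' @param eer_step Threshold sweep step, see [eer()].
#' @return A list of class `"fv_config"`.
#' @export
fv_config <- function(preset = "none", method = c("rlf", "mean_curvature"),
                      curvature_sigma = 2, curvature_epsilon = NULL,
                      canny_sigma = 1.5, canny_low = 0.7, canny_high = 0.9,
                      thetas = rlf_thetas(), cw = 30L, ch = 30L,
                      eer_step = 1e-4) {
  method <- match.arg(method)
  bad <- setdiff(as.integer(thetas), rlf_thetas())
  if (length(bad) > 0L) {
    stop("invalid value for `thetas`: ", paste(bad, collapse = ", "),
         " (must be multiples of 45 in [0, 315])", call. = FALSE)
  }
  structure(
    list(preset = preset, method = method,
         curvature_sigma = curvature_sigma,
         curvature_epsilon = curvature_epsilon,
         canny_sigma = canny_sigma, canny_low = canny_low,
         canny_high = canny_high, thetas = as.integer(thetas),
         cw = as.integer(cw), ch = as.integer(ch), eer_step = eer_step),
    class = "fv_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [fv_config()] grouped by stage:
#' `preprocess.preset`, `curvature.sigma`, `curvature.epsilon`,
#' `rlf.thetas`, `rlf.canny_sigma`, `rlf.canny_low`, `rlf.canny_high`,
#' `matching.cw`, `matching.ch`, `eval.step`, `method`. Missing keys keep
#' their defaults; unknown keys raise an error naming the key.
#'
#' @param path Path to a YAML file.
#' @return An `"fv_config"` object.
#' @export
read_fv_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- list(
    "method" = "method",
    "preprocess.preset" = "preset",
    "curvature.sigma" = "curvature_sigma",
    "curvature.epsilon" = "curvature_epsilon",
    "rlf.thetas" = "thetas",
    "rlf.canny_sigma" = "canny_sigma",
    "rlf.canny_low" = "canny_low",
    "rlf.canny_high" = "canny_high",
    "matching.cw" = "cw",
    "matching.ch" = "ch",
    "eval.step" = "eer_step"
  )
  flat <- list()
  for (grp in names(raw)) {
    if (is.list(raw[[grp]])) {
      for (key in names(raw[[grp]])) {
        flat[[paste(grp, key, sep = ".")]] <- raw[[grp]][[key]]
      }
    } else {
      flat[[grp]] <- raw[[grp]]
    }
  }
  unknown <- setdiff(names(flat), names(known))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(flat, unlist(known[names(flat)]))
  do.call(fv_config, args)
}

#' Extract vein features from one image
#'
#' Runs the full feature-extraction chain on an intensity image: database
#' preset (crop/rotate/scale), mean-curvature valley response, and — for the
#' RLF method — Canny knots plus Radon-like aggregation over the configured
#' directions; finally min-max normalization and Otsu binarization.
#'
#' @param img Numeric intensity matrix (as from [load_gray_image()]).
#' @param config An [fv_config()] object.
#' @return A list of class `"fv_features"` with `response` (valley response),
#'   `edges` and `rlf` (`NULL` for the baseline method), `pattern`
#'   (binary `"fv_pattern"`), and `config`.
#' @export
extract_features <- function(img, config = fv_config()) {
  stopifnot(is.matrix(img))
  img <- crop_and_scale(img, db_preset(config$preset))
  response <- vein_response(
    mean_curvature(img, sigma = config$curvature_sigma,
                   epsilon = config$curvature_epsilon))
  if (config$method == "rlf") {
    edges <- edge_map(response, low = config$canny_low,
                      high = config$canny_high, sigma = config$canny_sigma)
    stack <- rlf_stack(response, edges, config$thetas)
    pattern <- vein_pattern(stack$mean)
  } else {
    edges <- NULL
    stack <- NULL
    pattern <- vein_pattern(response)
  }
  structure(list(response = response, edges = edges, rlf = stack,
                 pattern = pattern, config = config),
            class = "fv_features")
}

#' Extract binary patterns for every image of a dataset
#'
#' Accepts either a dataset directory (`root/<class>/<image>.png`, as written
#' by [make_dataset()]) or an in-memory dataset from [generate_dataset()],
#' and returns the binary vein pattern of every image, organized by class.
#'
#' @param dataset Directory path or [generate_dataset()] result.
#' @param config An [fv_config()] object.
#' @return Named list of classes, each a named list of `"fv_pattern"`
#'   matrices, ready for [build_score_table()].
#' @export
extract_dataset_patterns <- function(dataset, config = fv_config()) {
  if (is.character(dataset)) {
    stopifnot(dir.exists(dataset))
    class_dirs <- list.dirs(dataset, recursive = FALSE)
    class_dirs <- class_dirs[basename(class_dirs) != "masks"]
    dataset <- lapply(stats::setNames(class_dirs, basename(class_dirs)),
                      function(d) {
                        files <- sort(list.files(d, pattern = "\\.(png|bmp)$",
                                                 full.names = TRUE))
                        lapply(stats::setNames(files,
                                               sub("\\.[^.]+$", "",
                                                   basename(files))),
                               load_gray_image)
                      })
  } else {
    dataset <- lapply(dataset, function(cl) {
      lapply(cl, function(inst) if (is.list(inst)) inst$image else inst)
    })
  }
  lapply(dataset, function(cl) {
    lapply(cl, function(img) extract_features(img, config)$pattern)
  })
}

#' Run the full verification experiment on a dataset
#'
#' Feature extraction for every image, the first-image-as-template
#' genuine/impostor protocol, and the FAR/FRR threshold sweep.
#'
#' @inheritParams extract_dataset_patterns
#' @return An `"fv_eer"` object (see [eer()]) with the `"fv_scores"` table
#'   attached as `$scores`.
#' @export
run_verification <- function(dataset, config = fv_config()) {
  patterns <- extract_dataset_patterns(dataset, config)
  scores <- build_score_table(patterns,
                              match_config(cw = config$cw, ch = config$ch))
  res <- eer(scores, step = config$eer_step)
  res$scores <- scores
  res
}
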