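#' Pipeline configuration
#'
#' Reads (or validates) the nested configuration driving [run_pipeline()]:
#' an `enhancement` block (see [enhancement_config()]; `enabled` turns the
#' whole step on or off), a `detection` block (`backend` = `"oracle"` or
#' `"threshold"`, `score_threshold`, backend options), a `cascade` block
#' (`model` path to a saved cascade, or `data` path to a training CSV plus
#' optional `families` / split fractions / `depth_col`), and a `seed`.
#'
#' @param x a YAML file path or a named list with the blocks above.
#' @return A list of class `pipeline_config` with all defaults filled in.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  enh <- cfg$enhancement %||% list()
  det <- cfg$detection %||% list()
  cas <- cfg$cascade %||% list()
  enh_cfg <- enhancement_config(
    sharpen_kernel = if (!is.null(enh$kernel))
      matrix(unlist(enh$kernel), nrow = length(enh$kernel), byrow = TRUE)
      else matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3),
    ccm = if (!is.null(enh$ccm))
      matrix(unlist(enh$ccm), nrow = 3, byrow = TRUE) else cbind(diag(3), 0),
    offsets = enh$offsets %||% rep(0, 4),
    gamma = enh$gamma %||% 2.2,
    alpha = enh$alpha %||% 1.3,
    beta = enh$beta %||% 10,
    enabled = isTRUE(enh$enabled %||% FALSE))
  backend <- match.arg(det$backend %||% "threshold", c("threshold", "oracle"))
  structure(list(
    enhancement = enh_cfg,
    detection = list(backend = backend,
                     score_threshold = det$score_threshold %||% 0.8,
                     threshold = det$threshold %||% 40,
                     min_area = det$min_area %||% 30,
                     annotations = det$annotations),
    cascade = cas,
    seed = cfg$seed %||% 1L),
    class = "pipeline_config")
}

#' Run the full weight-estimation pipeline on a directory of frames
#'
#' Executes the evaluation chain end to end: list frames, optionally
#' enhance each image, detect fish, keep detections scoring at least the
#' configured threshold (default 0.8), extract pixel sizes from the
#' boxes, then run the regression cascade (depth, centimetre size,
#' weight). A log line with input/output counts is emitted per step.
#' When no fish is detected anywhere the result has zero rows and a
#' warning is raised, not an error.
#'
#' @param config a [pipeline_config()] (or list/YAML path coerced to
#'   one).
#' @param frames_dir directory of PNG frames, or a list of `aqw_scene`
#'   objects (the oracle backend needs scenes or a VIA annotation file
#'   configured under `detection$annotations`).
#' @param age_weeks fish age supplied by the operator (weeks); recycled
#'   over all detections.
#' @param model a fitted [fish_cascade()]; overrides the config's
#'   `cascade$model` path. When neither is given but `cascade$data`
#'   points to a training CSV, a cascade is trained first.
#' @param out optional path; when given, results are written there as
#'   CSV via [write_results()].
#' @return data.frame of per-fish estimates (see [write_results()] for
#'   columns), invisibly also written to `out` when requested.
#' @export
run_pipeline <- function(config, frames_dir, age_weeks, model = NULL,
                         out = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  # resolve the cascade
  if (is.null(model)) {
    cas <- config$cascade
    if (!is.null(cas$model)) {
      model <- load_cascade(cas$model)
    } else if (!is.null(cas$data)) {
      message("[cascade] training from ", cas$data)
      dat <- read.csv(cas$data, stringsAsFactors = FALSE)
      fams <- unlist(cas$families %||%
                       c(depth = "svr", size = "lr", weight = "lr"))
      model <- fish_cascade(dat, families = fams,
                            depth_col = cas$depth_col %||% "depth_label_cm",
                            seed = config$seed)
    } else {
      stop("no cascade available: supply 'model', or set cascade$model ",
           "(saved model path) or cascade$data (training CSV) in the config",
           call. = FALSE)
    }
  }
  # assemble the frame sources
  if (is.character(frames_dir)) {
    paths <- sort(list.files(frames_dir, pattern = "\\.png$",
                             full.names = TRUE))
    frames <- lapply(paths, read_frame_png)
    names(frames) <- basename(paths)
  } else {
    frames <- frames_dir
    if (inherits(frames, "aqw_scene")) frames <- list(frames)
    if (is.null(names(frames)))
      names(frames) <- sprintf("frame_%04d", seq_along(frames))
  }
  message("[frames] ", length(frames), " frame(s)")
  all_rows <- list()
  n_det_total <- 0L
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    img <- if (inherits(fr, "aqw_scene")) fr$image else fr
    if (config$enhancement$enabled) img <- enhance(img, config$enhancement)
    dets <- if (config$detection$backend == "oracle") {
      if (!inherits(fr, "aqw_scene"))
        stop("oracle detector needs aqw_scene inputs", call. = FALSE)
      detect_oracle(fr, seed = config$seed)
    } else {
      detect_threshold(img, threshold = config$detection$threshold,
                       min_area = config$detection$min_area)
    }
    n_raw <- nrow(dets)
    dets <- filter_by_score(dets, config$detection$score_threshold)
    message(sprintf("[detect] %s: %d detection(s), %d passed score >= %.2f",
                    names(frames)[fi], n_raw, nrow(dets),
                    config$detection$score_threshold))
    if (nrow(dets) == 0L) next
    n_det_total <- n_det_total + nrow(dets)
    sizes <- lapply(seq_len(nrow(dets)),
                    function(i) bbox_to_size(dets[i, ]))
    obs <- data.frame(
      fish_id = sprintf("%s_det%02d", names(frames)[fi], seq_len(nrow(dets))),
      age_weeks = age_weeks,
      length_px = vapply(sizes, `[[`, numeric(1), "length_px"),
      width_px = vapply(sizes, `[[`, numeric(1), "width_px"),
      stringsAsFactors = FALSE)
    est <- predict(model, obs)
    all_rows[[length(all_rows) + 1L]] <- cbind(obs, est)
  }
  if (length(all_rows) == 0L) {
    warning("no detections passed the score filter; empty result")
    res <- data.frame(fish_id = character(), age_weeks = numeric(),
                      length_px = numeric(), width_px = numeric(),
                      depth_est_cm = numeric(), length_est_cm = numeric(),
                      width_est_cm = numeric(), weight_est_g = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, all_rows)
    rownames(res) <- NULL
  }
  message("[estimate] ", nrow(res), " fish estimated from ",
          n_det_total, " detection(s)")
  if (!is.null(out)) {
    write_results(res, out)
    message("[write] ", out)
  }
  res
}
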