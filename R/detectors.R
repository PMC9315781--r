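#' Detector backends
#'
#' The pipeline treats the fish detector as pluggable: anything that maps
#' an image to a data.frame of scored boxes (`x_min`, `y_min`, `x_max`,
#' `y_max`, `score`) can stand in for a trained network. Two backends
#' ship with the package.
#'
#' `detect_oracle()` reads the ground-truth annotations of a synthetic
#' scene, optionally jittering each box edge with Gaussian noise of SD
#' `jitter_sd` pixels and drawing scores uniformly from `score_range`.
#' With zero jitter it returns the annotations verbatim (score 0.99),
#' which pins down the rest of the pipeline in tests.
#'
#' `detect_threshold()` is a classical image-processing detector:
#' background subtraction against a reference frame (or the scene's
#' median intensity), binarization at `threshold`, connected-component
#' labelling, and one box per component of at least `min_area` pixels,
#' scored by the component's solidity (area over bounding-box area)
#' normalized by the fill ratio pi/4 of an ideal elliptical fish body,
#' so a clean single-fish component scores near 1.
#'
#' @param scene an `aqw_scene` from [render_scene()].
#' @param jitter_sd SD in pixels of the edge jitter (0 = exact boxes).
#' @param score_range range of the simulated confidence scores when
#'   jitter is nonzero.
#' @param seed integer seed or `NULL`.
#' @return A data.frame of detections, possibly with zero rows.
#' @export
detect_oracle <- function(scene, jitter_sd = 0,
                          score_range = c(0.8, 1), seed = NULL) {
  stopifnot(inherits(scene, "aqw_scene"))
  ann <- scene$annotations
  if (nrow(ann) == 0L)
    return(data.frame(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      score = numeric()))
  with_seed(seed, {
    n <- nrow(ann)
    H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
    out <- data.frame(x_min = as.numeric(ann$x_min),
                      y_min = as.numeric(ann$y_min),
                      x_max = as.numeric(ann$x_max),
                      y_max = as.numeric(ann$y_max),
                      score = rep(0.99, n))
    if (jitter_sd > 0) {
      out$x_min <- pmax(0, out$x_min + rnorm(n, 0, jitter_sd))
      out$y_min <- pmax(0, out$y_min + rnorm(n, 0, jitter_sd))
      out$x_max <- pmin(W, pmax(out$x_min + 1, out$x_max + rnorm(n, 0, jitter_sd)))
      out$y_max <- pmin(H, pmax(out$y_min + 1, out$y_max + rnorm(n, 0, jitter_sd)))
      out$score <- runif(n, score_range[1], score_range[2])
    }
    out
  })
}

#' @rdname detect_oracle
#' @param image an H x W x 3 array, or an `aqw_scene` whose image is used.
#' @param background optional H x W x 3 reference array (e.g. a rendered
#'   fish-free scene); when `NULL` the per-channel median of the image
#'   serves as the background estimate.
#' @param threshold minimum mean absolute channel difference (0-255) for
#'   a pixel to count as foreground.
#' @param min_area smallest connected component, in pixels, kept as a
#'   detection.
#' @export
detect_threshold <- function(image, background = NULL, threshold = 40,
                             min_area = 30) {
  if (inherits(image, "aqw_scene")) image <- image$image
  check_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(background)) {
    bg <- vapply(1:3, function(ch) stats::median(image[, , ch]), numeric(1))
    diff <- abs(sweep(image, 3, bg))
  } else {
    check_image(background)
    diff <- abs(image - background)
  }
  fg <- (diff[, , 1] + diff[, , 2] + diff[, , 3]) / 3 > threshold
  labels <- EBImage::bwlabel(fg * 1)
  n_comp <- max(labels)
  empty <- data.frame(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      score = numeric())
  if (n_comp == 0L) return(empty)
  rows <- lapply(seq_len(n_comp), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])
    # solidity relative to an ideal elliptical fish body (fill ratio pi/4)
    solidity <- nrow(idx) / ((y1 - y0) * (x1 - x0))
    data.frame(x_min = x0, y_min = y0, x_max = x1, y_max = y1,
               score = min(solidity / (pi / 4), 1))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
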