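#' Bounding boxes, size extraction, and score filtering
#'
#' Boxes are axis-aligned rectangles in 0-based, half-open pixel
#' coordinates: columns (or named entries) `x_min`, `y_min`, `x_max`,
#' `y_max` with `x_max > x_min` and `y_max > y_min`. Detections add a
#' `score` column in [0, 1].
#'
#' `bbox_to_size()` reads fish dimensions off a box: length is the
#' horizontal extent and width the vertical extent, fish being assumed to
#' swim roughly horizontally; when the box is taller than wide the two are
#' swapped and `swapped = TRUE` is flagged instead of failing.
#' `filter_by_score()` keeps detections whose score is greater than or
#' equal to the threshold (the pipeline default is 0.8), preserving order.
#'
#' @param bbox a length-4 named numeric vector, one-row data.frame, or
#'   list with `x_min`, `y_min`, `x_max`, `y_max`.
#' @return `bbox_to_size()`: list with `length_px`, `width_px`, `swapped`.
#' @examples
#' bbox_to_size(c(x_min = 10, y_min = 20, x_max = 110, y_max = 60))
#' @export
bbox_to_size <- function(bbox) {
  b <- as_bbox(bbox)
  h <- b["x_max"] - b["x_min"]
  v <- b["y_max"] - b["y_min"]
  if (h <= 0 || v <= 0) stop("degenerate bounding box", call. = FALSE)
  if (v > h) list(length_px = unname(v), width_px = unname(h), swapped = TRUE)
  else list(length_px = unname(h), width_px = unname(v), swapped = FALSE)
}

as_bbox <- function(bbox) {
  if (is.data.frame(bbox)) bbox <- unlist(bbox[1, c("x_min", "y_min", "x_max", "y_max")])
  if (is.list(bbox)) bbox <- unlist(bbox)
  if (is.null(names(bbox)) && length(bbox) == 4L)
    names(bbox) <- c("x_min", "y_min", "x_max", "y_max")
  b <- bbox[c("x_min", "y_min", "x_max", "y_max")]
  if (any(is.na(b))) stop("bbox needs x_min, y_min, x_max, y_max", call. = FALSE)
  b
}

#' @rdname bbox_to_size
#' @param dets data.frame of detections with a `score` column.
#' @param threshold minimum score to keep, in [0, 1].
#' @export
filter_by_score <- function(dets, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  dets[dets$score >= threshold, , drop = FALSE]
}

#' Intersection over union of two boxes
#'
#' @param b1,b2 boxes as in [bbox_to_size()].
#' @return Overlap ratio in [0, 1]; 0 for disjoint boxes.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(b1, b2) {
  a <- as_bbox(b1); b <- as_bbox(b2)
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"])
  area_b <- (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
  unname(inter / (area_a + area_b - inter))
}

# Vectorized IoU of one box against a matrix of boxes (rows).
iou_one_many <- function(b, m) {
  iw <- pmin(b[3], m[, 3]) - pmax(b[1], m[, 1])
  ih <- pmin(b[4], m[, 4]) - pmax(b[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / ((b[3] - b[1]) * (b[4] - b[2]) +
             (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter)
}

#' COCO-style average precision for fish detection
#'
#' Matches detections to ground truths greedily in descending score order
#' (ties broken by input order); each ground truth can be matched at most
#' once, and a detection matches the ground truth of highest IoU at or
#' above the threshold. The precision-recall curve is integrated by
#' 101-point interpolation. `ap_summary()` reports AP averaged over the
#' IoU thresholds 0.50 to 0.95 in steps of 0.05 (the primary COCO metric)
#' together with AP50 and AP75. When detections and ground truths span
#' several images, an `image_id` column keeps matches within images.
#'
#' With no ground truths and no detections the score is 1 by convention;
#' with detections but no ground truths it is 0.
#'
#' @param dets data.frame of detections (`x_min`, `y_min`, `x_max`,
#'   `y_max`, `score`, optional `image_id`).
#' @param gts data.frame of ground-truth boxes (same coordinate columns,
#'   optional `image_id`).
#' @param iou_threshold IoU above which a match counts as a true positive.
#' @return `average_precision()`: a single number in [0, 1].
#'   `ap_summary()`: named vector `c(AP, AP50, AP75)` on the 0-100 scale
#'   used in detection benchmarks.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  n_det <- if (is.null(dets)) 0L else nrow(dets)
  n_gt <- if (is.null(gts)) 0L else nrow(gts)
  if (n_gt == 0L) return(if (n_det == 0L) 1 else 0)
  if (n_det == 0L) return(0)
  det_img <- if ("image_id" %in% names(dets)) dets$image_id else rep(1L, n_det)
  gt_img <- if ("image_id" %in% names(gts)) gts$image_id else rep(1L, n_gt)
  ord <- order(-dets$score)
  dm <- as.matrix(dets[ord, c("x_min", "y_min", "x_max", "y_max")])
  det_img <- det_img[ord]
  gm <- as.matrix(gts[, c("x_min", "y_min", "x_max", "y_max")])
  gt_used <- logical(n_gt)
  tp <- numeric(n_det)
  for (i in seq_len(n_det)) {
    cand <- which(gt_img == det_img[i] & !gt_used)
    if (length(cand) == 0L) next
    ious <- iou_one_many(dm[i, ], gm[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- 1
      gt_used[cand[j]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_len(n_det)
  recall <- cum_tp / n_gt
  # 101-point interpolation: max precision at recall >= r for r = 0, .01, ..., 1
  rec_pts <- seq(0, 1, by = 0.01)
  p_interp <- rev(cummax(rev(precision)))
  idx <- findInterval(rec_pts, recall, left.open = TRUE) + 1L
  p_at <- ifelse(idx > n_det, 0, p_interp[pmin(idx, n_det)])
  mean(p_at)
}

#' @rdname average_precision
#' @param config list with `iou_thresholds` (default `seq(0.5, 0.95,
#'   0.05)`) as in detection benchmark conventions.
#' @export
ap_summary <- function(dets, gts, config = list(iou_thresholds = seq(0.5, 0.95, by = 0.05))) {
  thr <- config$iou_thresholds %||% seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thr, function(t) average_precision(dets, gts, t), numeric(1))
  c(AP = 100 * mean(aps),
    AP50 = 100 * average_precision(dets, gts, 0.50),
    AP75 = 100 * average_precision(dets, gts, 0.75))
}
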