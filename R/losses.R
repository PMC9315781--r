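#' Detector training losses
#'
#' Pure, evaluable forms of the multi-task loss used when training an
#' instance-segmentation fish detector: a classification term, a smooth-L1
#' bounding-box regression term, and an average binary cross-entropy mask
#' term, summed (with configurable weights) into the total loss.
#'
#' `class_loss(p_u)` is the negative natural log of the predicted
#' probability of the true class. `smooth_l1(x)` is `0.5 x^2` for
#' `|x| < 1` and `|x| - 0.5` otherwise; `bbox_loss()` sums it over the
#' four box coordinates (x, y, w, h). `mask_loss()` is the two-term
#' binary cross-entropy averaged over the m x m mask pixels.
#'
#' @param p_u predicted probability of the ground-truth class, in (0, 1].
#' @return A single nonnegative number.
#' @examples
#' class_loss(exp(-1))          # 1
#' bbox_loss(c(0, 0, 0, 2), c(0, 0, 0, 0))  # 1.5
#' @export
class_loss <- function(p_u) {
  if (any(p_u <= 0) || any(p_u > 1))
    stop("p_u must be in (0, 1]", call. = FALSE)
  -log(p_u)
}

#' @rdname class_loss
#' @param x numeric vector of residuals.
#' @export
smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)

#' @rdname class_loss
#' @param t_u predicted box as a 4-vector (x, y, w, h).
#' @param v ground-truth box, same layout.
#' @export
bbox_loss <- function(t_u, v) {
  stopifnot(length(t_u) == 4L, length(v) == 4L)
  sum(smooth_l1(t_u - v))
}

#' @rdname class_loss
#' @param pred_mask m x m matrix of per-pixel foreground probabilities
#'   in (0, 1).
#' @param true_mask m x m binary matrix (0/1 ground-truth mask).
#' @export
mask_loss <- function(pred_mask, true_mask) {
  pred_mask <- as.matrix(pred_mask); true_mask <- as.matrix(true_mask)
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("mask shapes differ", call. = FALSE)
  if (any(pred_mask <= 0) || any(pred_mask >= 1))
    stop("pred_mask values must be in (0, 1)", call. = FALSE)
  if (!all(true_mask %in% c(0, 1)))
    stop("true_mask must be binary", call. = FALSE)
  -mean(true_mask * log(pred_mask) + (1 - true_mask) * log(1 - pred_mask))
}

#' @rdname class_loss
#' @param l_class,l_bb,l_mask nonnegative loss components.
#' @param weights length-3 weight vector (defaults to unweighted sum).
#' @export
total_loss <- function(l_class, l_bb, l_mask, weights = c(1, 1, 1)) {
  if (any(c(l_class, l_bb, l_mask) < 0))
    stop("loss components must be nonnegative", call. = FALSE)
  stopifnot(length(weights) == 3L)
  weights[1] * l_class + weights[2] * l_bb + weights[3] * l_mask
}
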