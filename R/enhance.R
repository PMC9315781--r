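#' Sample frame indices from a video
#'
#' Reduces a continuous recording to a discrete series by taking one frame
#' every `period_s` seconds: indices `round(k * period_s * fps)` for
#' k = 0, 1, ... while the index is inside the recording.
#'
#' @param fps frames per second of the source video.
#' @param period_s sampling period in seconds (1 = one frame per second).
#' @param duration_s recording length in seconds.
#' @return Integer vector of 0-based frame indices (empty for duration 0).
#' @examples
#' sample_frames(60, 1, 10)  # 0, 60, ..., 540
#' @export
sample_frames <- function(fps, period_s, duration_s) {
  stopifnot(fps > 0, period_s > 0, duration_s >= 0)
  n_frames <- duration_s * fps
  if (n_frames <= 0) return(integer(0))
  k <- 0:ceiling(n_frames / (period_s * fps))
  idx <- round_half_up(k * period_s * fps)
  as.integer(idx[idx < n_frames])
}

#' Turbid-water image enhancement configuration
#'
#' Bundles the parameters of the three-step enhancement chain applied to
#' frames from turbid (biofloc) water: spatial sharpening, a colour
#' correction matrix over the red/green/blue/white components, and a
#' linear exposure adjustment. All parameters are overridable; the
#' defaults are chosen to counteract the blur, green cast, and contrast
#' loss of the synthetic turbidity model.
#'
#' @param sharpen_kernel odd-sized numeric matrix used as the correlation
#'   kernel; the default is the standard 3x3 sharpening filter.
#' @param ccm 3 x 4 colour correction matrix acting on (R, G, B, W) with
#'   W the mean of the three channels; default passes RGB through.
#' @param offsets length-4 offset vector subtracted from (R, G, B, W) on
#'   the normalized [0, 1] scale before the matrix.
#' @param gamma gamma of the power correction applied after the matrix.
#' @param alpha exposure gain (> 0).
#' @param beta exposure bias, in 8-bit intensity units.
#' @param enabled logical; [enhance()] returns its input untouched when
#'   `FALSE` (turbid-water enhancement is optional in the pipeline).
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(sharpen_kernel = matrix(c(0, -1, 0,
                                                         -1, 5, -1,
                                                         0, -1, 0), 3, 3),
                               ccm = cbind(diag(3), 0),
                               offsets = rep(0, 4),
                               gamma = 2.2, alpha = 1.3, beta = 10,
                               enabled = TRUE) {
  sharpen_kernel <- as.matrix(sharpen_kernel)
  if (any(dim(sharpen_kernel) %% 2 == 0))
    stop("sharpen_kernel must have odd dimensions", call. = FALSE)
  ccm <- as.matrix(ccm)
  stopifnot(identical(dim(ccm), c(3L, 4L)), length(offsets) == 4,
            gamma > 0, alpha > 0, is.logical(enabled))
  structure(list(sharpen_kernel = sharpen_kernel, ccm = ccm,
                 offsets = as.numeric(offsets), gamma = gamma,
                 alpha = alpha, beta = beta, enabled = enabled),
            class = "enhancement_config")
}

identity_enhancement <- function() {
  enhancement_config(sharpen_kernel = matrix(1, 1, 1), ccm = cbind(diag(3), 0),
                     offsets = rep(0, 4), gamma = 1, alpha = 1, beta = 0)
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  invisible(TRUE)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

# 2-D correlation of a matrix with an odd-sized kernel, replicate padding.
# Vectorized as a sum of shifted padded slices (one term per kernel entry).
correlate2d <- function(mat, kernel) {
  a <- (nrow(kernel) - 1L) %/% 2L  # half-extent along x (rows)
  b <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- pmin(pmax(seq_len(nr + 2L * a) - a, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * b) - b, 1L), nc)
  pad <- mat[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel)))
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w != 0)
        out <- out + w * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  out
}

#' Enhancement operators: sharpening, colour correction, exposure
#'
#' `sharpen()` correlates each channel with an odd-sized kernel under
#' replicate border padding. `apply_ccm()` normalizes the channels to
#' [0, 1], forms the four-component vector (R, G, B, W) with W the channel
#' mean, subtracts the offsets, applies the 3 x 4 colour correction
#' matrix, clips negatives to zero, raises to `1/gamma`, and rescales to
#' 8 bits. `adjust_exposure()` applies `alpha * value + beta` per channel.
#' All three clip to [0, 255] and round to the nearest integer (ties away
#' from zero), so outputs remain valid 8-bit images.
#'
#' @param image an H x W x 3 numeric array with values in [0, 255].
#' @param kernel odd-sized numeric correlation kernel.
#' @return An H x W x 3 array of the same shape, integer-valued in
#'   [0, 255].
#' @examples
#' img <- array(100, c(4, 4, 3))
#' identical(sharpen(img, matrix(c(0,-1,0,-1,5,-1,0,-1,0), 3, 3)), img * 1)
#' @export
sharpen <- function(image, kernel) {
  check_image(image)
  kernel <- as.matrix(kernel)
  if (any(dim(kernel) %% 2 == 0))
    stop("kernel must have odd dimensions", call. = FALSE)
  out <- image
  for (ch in 1:3)
    out[, , ch] <- round_half_up(clip8(correlate2d(image[, , ch], kernel)))
  out
}

#' @rdname sharpen
#' @param ccm 3 x 4 numeric colour correction matrix.
#' @param offsets length-4 numeric offset vector on the [0, 1] scale.
#' @param gamma positive gamma for the power correction.
#' @export
apply_ccm <- function(image, ccm, offsets = rep(0, 4), gamma = 1) {
  check_image(image)
  ccm <- as.matrix(ccm)
  stopifnot(identical(dim(ccm), c(3L, 4L)), length(offsets) == 4, gamma > 0)
  d <- dim(image)
  s <- matrix(image, ncol = 3) / 255           # npix x 3, columns R G B
  s4 <- cbind(s, rowMeans(s))                  # append white component
  s4 <- sweep(s4, 2, as.numeric(offsets))
  out <- tcrossprod(s4, ccm)                   # npix x 3
  out[out < 0] <- 0                            # clip before the root
  out <- out^(1 / gamma)
  array(round_half_up(clip8(out * 255)), d)
}

#' @rdname sharpen
#' @param alpha exposure gain (> 0).
#' @param beta exposure bias in intensity units.
#' @export
adjust_exposure <- function(image, alpha, beta = 0) {
  check_image(image)
  if (alpha <= 0) stop("alpha (gain) must be > 0", call. = FALSE)
  array(round_half_up(clip8(alpha * image + beta)), dim(image))
}

#' @rdname sharpen
#' @param config an [enhancement_config()].
#' @export
enhance <- function(image, config = enhancement_config()) {
  stopifnot(inherits(config, "enhancement_config"))
  if (!config$enabled) return(image)
  image <- sharpen(image, config$sharpen_kernel)
  image <- apply_ccm(image, config$ccm, config$offsets, config$gamma)
  adjust_exposure(image, config$alpha, config$beta)
}
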