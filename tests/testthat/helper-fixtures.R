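# Shared fixtures: a small camera keeps rendered scenes fast, and the
# reduced-variation growth model is the "all noise off" configuration used
# by the recovery tests (pixel noise 0, unquantized depth labels, a tenth
# of the calibrated individual variation).

small_camera <- function() {
  camera_model(focal_px = 200, image_width_px = 320, image_height_px = 180,
               depth_min_cm = 20, depth_max_cm = 60)
}

low_variation_growth <- function(factor = 0.1) {
  growth_model(anchor_sd_weights_g = c(26.38, 91.64) * factor)
}

# brute-force double-loop correlation with replicate padding: the oracle
# the vectorized sharpen() must agree with
correlate_naive <- function(mat, kernel) {
  a <- (nrow(kernel) - 1L) %/% 2L
  b <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (x in seq_len(nr)) for (y in seq_len(nc)) {
    acc <- 0
    for (dx in -a:a) for (dy in -b:b) {
      xx <- min(max(x + dx, 1L), nr)
      yy <- min(max(y + dy, 1L), nc)
      acc <- acc + kernel[dx + a + 1L, dy + b + 1L] * mat[xx, yy]
    }
    out[x, y] <- acc
  }
  out
}

# pixel-rasterization IoU oracle for integer boxes
iou_raster <- function(b1, b2) {
  lim <- max(b1, b2) + 1L
  g1 <- matrix(FALSE, lim, lim); g2 <- matrix(FALSE, lim, lim)
  if (b1[3] > b1[1] && b1[4] > b1[2])
    g1[(b1[1] + 1):b1[3], (b1[2] + 1):b1[4]] <- TRUE
  if (b2[3] > b2[1] && b2[4] > b2[2])
    g2[(b2[1] + 1):b2[3], (b2[2] + 1):b2[4]] <- TRUE
  u <- sum(g1 | g2)
  if (u == 0) return(0)
  sum(g1 & g2) / u
}
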