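#' Render a synthetic underwater scene
#'
#' Draws each observed fish as a filled ellipse of its projected pixel
#' dimensions at a reproducible random position in the frame, over a dark
#' noisy background, and records exact ground-truth bounding boxes.
#' Turbidity (0 = clear, 1 = fully turbid) degrades the pixels the way
#' biofloc water does — Gaussian blur, a green-channel cast, and contrast
#' compression scaled by the turbidity value — but never the annotations.
#' Overlapping placements are allowed, emulating scenes with multiple
#' overlapping fish.
#'
#' @param fish_obs data.frame of observations (rows as from [observe()]);
#'   only `fish_id`, `age_weeks`, `length_px`, `width_px`,
#'   `depth_label_cm` are used. May have zero rows.
#' @param camera a [camera_model()]; sets the frame size.
#' @param turbidity real in [0, 1].
#' @param seed integer seed or `NULL`.
#' @return An object of class `aqw_scene`: list with `image` (H x W x 3
#'   integer-valued array in [0, 255]), `annotations` (data.frame with
#'   `fish_id`, `x_min`, `y_min`, `x_max`, `y_max`, `depth_label_cm`,
#'   `age_weeks`; 0-based half-open pixel coordinates), and `turbidity`.
#' @export
render_scene <- function(fish_obs, camera = camera_model(),
                         turbidity = 0, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"),
            turbidity >= 0, turbidity <= 1)
  H <- camera$image_height_px; W <- camera$image_width_px
  n <- if (is.null(fish_obs)) 0L else nrow(fish_obs)
  with_seed(seed, {
    img <- array(0, c(H, W, 3))
    base <- 45
    img[, , 1] <- base + matrix(rnorm(H * W, 0, 4), H, W)
    img[, , 2] <- base + 8 + matrix(rnorm(H * W, 0, 4), H, W)
    img[, , 3] <- base + 15 + matrix(rnorm(H * W, 0, 4), H, W)
    ann <- data.frame(fish_id = character(), x_min = integer(),
                      y_min = integer(), x_max = integer(),
                      y_max = integer(), depth_label_cm = numeric(),
                      age_weeks = integer(), stringsAsFactors = FALSE)
    if (n > 0L) {
      for (i in seq_len(n)) {
        lw <- round_half_up(fish_obs$length_px[i])
        wh <- round_half_up(fish_obs$width_px[i])
        lw <- min(max(lw, 2), W); wh <- min(max(wh, 2), H)
        x0 <- floor(runif(1, 0, W - lw + 1))
        y0 <- floor(runif(1, 0, H - wh + 1))
        cx <- x0 + lw / 2; cy <- y0 + wh / 2
        # filled ellipse, bright body with a mild per-fish tint
        xs <- (x0 + 1):(x0 + lw); ys <- (y0 + 1):(y0 + wh)
        ex <- (xs - 0.5 - cx) / (lw / 2)
        ey <- (ys - 0.5 - cy) / (wh / 2)
        inside <- outer(ey^2, ex^2, `+`) <= 1     # rows = y, cols = x
        tone <- 170 + runif(1, -15, 15)
        for (ch in 1:3) {
          sub <- img[ys, xs, ch]
          sub[inside] <- tone + c(10, 0, -10)[ch]
          img[ys, xs, ch] <- sub
        }
        ann <- rbind(ann, data.frame(
          fish_id = as.character(fish_obs$fish_id[i]),
          x_min = x0, y_min = y0, x_max = x0 + lw, y_max = y0 + wh,
          depth_label_cm = fish_obs$depth_label_cm[i],
          age_weeks = fish_obs$age_weeks[i], stringsAsFactors = FALSE))
      }
    }
    if (turbidity > 0) img <- apply_turbidity(img, turbidity)
    img <- array(round_half_up(clip8(img)), c(H, W, 3))
    structure(list(image = img, annotations = ann, turbidity = turbidity),
              class = "aqw_scene")
  })
}

# Degrade an image like turbid biofloc water: blur, green cast, contrast
# compression, each scaled by turbidity in [0, 1].
apply_turbidity <- function(img, turbidity) {
  sigma <- 3 * turbidity
  if (sigma > 0.1) {
    half <- max(1L, ceiling(2 * sigma))
    g <- exp(-((-half:half)^2) / (2 * sigma^2)); g <- g / sum(g)
    k <- outer(g, g)
    for (ch in 1:3) img[, , ch] <- correlate2d(img[, , ch], k)
  }
  img[, , 2] <- img[, , 2] + 40 * turbidity
  m <- mean(img)
  (1 - 0.6 * turbidity) * img + 0.6 * turbidity * m
}

#' @export
print.aqw_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<aqw_scene> %d x %d px, %d fish, turbidity %.2f\n",
              d[2], d[1], nrow(x$annotations), x$turbidity))
  invisible(x)
}

#' Write a scene to disk as PNG plus VIA-style annotations
#'
#' @param scene an `aqw_scene`.
#' @param image_path path of the PNG to write.
#' @param annotation_path optional path of a companion VIA-style JSON
#'   annotation file (see [write_via_annotations()]).
#' @return `image_path`, invisibly.
#' @export
write_scene_png <- function(scene, image_path, annotation_path = NULL) {
  stopifnot(inherits(scene, "aqw_scene"))
  png::writePNG(scene$image / 255, image_path)
  if (!is.null(annotation_path))
    write_via_annotations(scene$annotations, annotation_path,
                          filename = basename(image_path))
  invisible(image_path)
}

#' Read a PNG frame as an 8-bit RGB array
#'
#' @param path path to a PNG file.
#' @return An H x W x 3 array with values in [0, 255].
#' @export
read_frame_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round_half_up(x * 255)
}
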