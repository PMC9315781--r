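#' Growth model for a simulated Tilapia cohort
#'
#' Describes how weight varies with age over the monitored grow-out window.
#' The cohort is anchored at two weighings: mean weight 166.45 g (SD 26.38)
#' at 20 weeks and 482.24 g (SD 91.64) at 28 weeks; mean and SD are
#' interpolated linearly in age between the anchors. Length follows the
#' cube-law allometry \eqn{W = a L^3}; width is a fixed fraction of length.
#' The default `allometric_a` places lengths at roughly 20-28.5 cm and
#' widths at 7.6-10.8 cm, inside the 20-30 cm / 7-12 cm ranges measured on
#' the real fish.
#'
#' @param anchor_ages integer pair, weeks at the two anchor weighings.
#' @param anchor_mean_weights_g,anchor_sd_weights_g numeric pairs, grams.
#' @param allometric_a positive scalar of the cube law (g/cm^3).
#' @param width_ratio width as a fraction of length, in (0, 1).
#' @return A list of class `growth_model`.
#' @export
growth_model <- function(anchor_ages = c(20L, 28L),
                         anchor_mean_weights_g = c(166.45, 482.24),
                         anchor_sd_weights_g = c(26.38, 91.64),
                         allometric_a = 166.45 / 20^3,
                         width_ratio = 0.38) {
  stopifnot(length(anchor_ages) == 2L, anchor_ages[1] < anchor_ages[2],
            length(anchor_mean_weights_g) == 2L,
            anchor_mean_weights_g[1] < anchor_mean_weights_g[2],
            all(anchor_sd_weights_g > 0), allometric_a > 0,
            width_ratio > 0, width_ratio < 1)
  structure(list(anchor_ages = as.integer(anchor_ages),
                 anchor_mean_weights_g = anchor_mean_weights_g,
                 anchor_sd_weights_g = anchor_sd_weights_g,
                 allometric_a = allometric_a,
                 width_ratio = width_ratio),
            class = "growth_model")
}

# Linear-in-age interpolation of the anchor statistics.
growth_params_at_age <- function(growth, age_weeks) {
  a <- growth$anchor_ages
  t <- (age_weeks - a[1]) / (a[2] - a[1])
  list(mean = growth$anchor_mean_weights_g[1] +
         t * diff(growth$anchor_mean_weights_g),
       sd = growth$anchor_sd_weights_g[1] + t * diff(growth$anchor_sd_weights_g))
}

#' Pinhole camera model for underwater observation
#'
#' Perspective projection maps a true size to pixels as
#' `pixels = cm * focal_px / depth_cm`. The defaults describe a 1920 x 1080
#' recording with camera-to-fish depth between 5 and 60 cm, with reference
#' depth markers on the tank floor every 10 cm.
#'
#' @param focal_px focal length expressed in pixels.
#' @param image_width_px,image_height_px frame size in pixels.
#' @param depth_min_cm,depth_max_cm admissible camera-to-fish distances.
#' @param marker_spacing_cm spacing of the depth reference markers.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(focal_px = 1000,
                         image_width_px = 1920L, image_height_px = 1080L,
                         depth_min_cm = 5, depth_max_cm = 60,
                         marker_spacing_cm = 10) {
  stopifnot(focal_px > 0, image_width_px >= 1, image_height_px >= 1,
            depth_min_cm > 0, depth_min_cm < depth_max_cm,
            marker_spacing_cm > 0)
  structure(list(focal_px = focal_px,
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 depth_min_cm = depth_min_cm, depth_max_cm = depth_max_cm,
                 marker_spacing_cm = marker_spacing_cm),
            class = "camera_model")
}

#' Simulate a fish cohort
#'
#' Draws `n` fish with ages taken uniformly from `ages`. Weight is sampled
#' from a normal law truncated at zero whose mean and SD are the growth
#' model's linear-in-age interpolation between its anchors; length is
#' derived from weight through the cube-law allometry and width as a fixed
#' fraction of length.
#'
#' @param n number of fish.
#' @param ages integer vector of ages (weeks); must lie within the growth
#'   model's anchor span.
#' @param growth a [growth_model()].
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return A data.frame with columns `fish_id`, `age_weeks`, `length_cm`,
#'   `width_cm`, `weight_g`.
#' @examples
#' pop <- sample_population(5, ages = c(20, 28), seed = 1)
#' all(abs(pop$weight_g - growth_model()$allometric_a * pop$length_cm^3) < 1e-9)
#' @export
sample_population <- function(n, ages, growth = growth_model(), seed = NULL) {
  stopifnot(n >= 0, inherits(growth, "growth_model"))
  ages <- as.integer(ages)
  span <- growth$anchor_ages
  if (any(ages < span[1] | ages > span[2]))
    stop(sprintf("ages must lie within the anchor span [%d, %d] weeks",
                 span[1], span[2]), call. = FALSE)
  if (n == 0L)
    return(data.frame(fish_id = character(), age_weeks = integer(),
                      length_cm = numeric(), width_cm = numeric(),
                      weight_g = numeric(), stringsAsFactors = FALSE))
  with_seed(seed, {
    age <- if (length(ages) == 1L) rep(ages, n) else
      ages[sample.int(length(ages), n, replace = TRUE)]
    p <- growth_params_at_age(growth, age)
    w <- rnorm(n, p$mean, p$sd)
    # truncate at zero by resampling the (practically nonexistent) negatives
    bad <- which(w <= 0)
    while (length(bad) > 0L) {
      w[bad] <- rnorm(length(bad), p$mean[bad], p$sd[bad])
      bad <- bad[w[bad] <= 0]
    }
    len <- (w / growth$allometric_a)^(1 / 3)
    data.frame(fish_id = sprintf("fish_%05d", seq_len(n)),
               age_weeks = age, length_cm = len,
               width_cm = growth$width_ratio * len, weight_g = w,
               stringsAsFactors = FALSE)
  })
}

# Quantize a true depth to the nearest 10-cm marker; markers exist only at
# multiples of the spacing inside the camera's depth range.
quantize_depth <- function(depth_cm, camera) {
  sp <- camera$marker_spacing_cm
  lo <- sp * ceiling(camera$depth_min_cm / sp)
  hi <- sp * floor(camera$depth_max_cm / sp)
  pmin(pmax(sp * round_half_up(depth_cm / sp), lo), hi)
}

#' Observe one fish through the camera
#'
#' Projects the fish's true dimensions to pixels at the given depth
#' (`px = cm * focal / depth`), adds Gaussian pixel measurement noise, and
#' attaches the marker-quantized depth label a human annotator would have
#' recorded. An observation whose projected length would overflow the frame
#' width is rejected with a classed error (`aquaweight_projection_overflow`)
#' rather than silently dropped.
#'
#' @param fish a one-row data.frame as produced by [sample_population()].
#' @param camera a [camera_model()].
#' @param depth_cm true camera-to-fish distance; must be inside the
#'   camera's depth bounds.
#' @param pixel_noise_sd SD of the additive pixel measurement noise.
#' @param seed integer seed or `NULL`.
#' @return A one-row data.frame with columns `fish_id`, `age_weeks`,
#'   `length_px`, `width_px`, `depth_true_cm`, `depth_label_cm`,
#'   `length_cm`, `width_cm`, `weight_g`.
#' @export
observe <- function(fish, camera, depth_cm, pixel_noise_sd = 2, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"), nrow(fish) == 1L,
            pixel_noise_sd >= 0)
  if (depth_cm < camera$depth_min_cm || depth_cm > camera$depth_max_cm)
    stop(sprintf("depth %.3g cm outside camera bounds [%.3g, %.3g]",
                 depth_cm, camera$depth_min_cm, camera$depth_max_cm),
         call. = FALSE)
  scale <- camera$focal_px / depth_cm
  len_px0 <- fish$length_cm * scale
  if (len_px0 > camera$image_width_px)
    stop(structure(class = c("aquaweight_projection_overflow",
                             "error", "condition"),
                   list(message = sprintf(
                     "projected length %.1f px exceeds frame width %d px",
                     len_px0, camera$image_width_px),
                     call = NULL)))
  with_seed(seed, {
    noise <- if (pixel_noise_sd > 0) rnorm(2, 0, pixel_noise_sd) else c(0, 0)
    len_px <- max(len_px0 + noise[1], 1)
    wid_px <- max(fish$width_cm * scale + noise[2], 1)
    data.frame(fish_id = fish$fish_id, age_weeks = fish$age_weeks,
               length_px = len_px, width_px = wid_px,
               depth_true_cm = depth_cm,
               depth_label_cm = quantize_depth(depth_cm, camera),
               length_cm = fish$length_cm, width_cm = fish$width_cm,
               weight_g = fish$weight_g, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic annotation-file dataset
#'
#' Emulates the tabular training data of the weight-estimation pipeline:
#' each row is one annotated sighting carrying the fish's age, its pixel
#' and centimetre dimensions, its quantized depth label, and its true
#' weight. Depths are drawn uniformly over the camera bounds (before
#' quantization); a draw whose projection would overflow the frame is
#' redrawn so every row is complete.
#'
#' @param n number of rows.
#' @param camera a [camera_model()].
#' @param growth a [growth_model()].
#' @param ages ages to sample from; default every two weeks over the
#'   anchor span (the real cohort was recorded biweekly from week 20 to 28).
#' @param pixel_noise_sd SD of pixel measurement noise (default 2 px).
#' @param quantize should `depth_label_cm` be marker-quantized? With
#'   `FALSE` the label equals the true depth (a noiseless-labels setting
#'   used in recovery experiments).
#' @param seed integer seed or `NULL`.
#' @return A data.frame with one row per observation and columns `fish_id`,
#'   `age_weeks`, `length_px`, `width_px`, `depth_true_cm`,
#'   `depth_label_cm`, `length_cm`, `width_cm`, `weight_g`.
#' @examples
#' d <- make_file_dataset(100, seed = 7)
#' stopifnot(nrow(d) == 100, all(d$length_px > d$width_px))
#' @export
make_file_dataset <- function(n, camera = camera_model(),
                              growth = growth_model(),
                              ages = NULL, pixel_noise_sd = 2,
                              quantize = TRUE, seed = NULL) {
  stopifnot(n >= 0)
  if (is.null(ages))
    ages <- seq(growth$anchor_ages[1], growth$anchor_ages[2], by = 2L)
  cols <- c("fish_id", "age_weeks", "length_px", "width_px",
            "depth_true_cm", "depth_label_cm", "length_cm", "width_cm",
            "weight_g")
  if (n == 0L) {
    out <- data.frame(fish_id = character(), age_weeks = integer(),
                      length_px = numeric(), width_px = numeric(),
                      depth_true_cm = numeric(), depth_label_cm = numeric(),
                      length_cm = numeric(), width_cm = numeric(),
                      weight_g = numeric(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  with_seed(seed, {
    pop <- sample_population(n, ages, growth, seed = NULL)
    scale_min <- camera$focal_px / camera$image_width_px  # min depth per cm
    depth <- runif(n, camera$depth_min_cm, camera$depth_max_cm)
    # redraw depths that would project the fish wider than the frame
    lo <- pmax(pop$length_cm * scale_min, camera$depth_min_cm)
    bad <- which(depth * camera$image_width_px < pop$length_cm * camera$focal_px)
    for (i in bad) depth[i] <- runif(1, lo[i], camera$depth_max_cm)
    scale <- camera$focal_px / depth
    len_px <- pmax(pop$length_cm * scale + rnorm(n, 0, pixel_noise_sd), 1)
    wid_px <- pmax(pop$width_cm * scale + rnorm(n, 0, pixel_noise_sd), 1)
    data.frame(fish_id = pop$fish_id, age_weeks = pop$age_weeks,
               length_px = len_px, width_px = wid_px,
               depth_true_cm = depth,
               depth_label_cm = if (quantize) quantize_depth(depth, camera)
                                else depth,
               length_cm = pop$length_cm, width_cm = pop$width_cm,
               weight_g = pop$weight_g, stringsAsFactors = FALSE)[, cols]
  })
}
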