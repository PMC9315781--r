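test_that("cohort weights calibrate to the anchor statistics", {
  n <- 10000
  g <- growth_model()
  p20 <- sample_population(n, 20, g, seed = 1)
  p28 <- sample_population(n, 28, g, seed = 1)
  # standard-error tolerance: 3 * SD / sqrt(n)
  expect_equal(mean(p20$weight_g), 166.45, tolerance = 3 * 26.38 / sqrt(n) / 166.45)
  expect_equal(mean(p28$weight_g), 482.24, tolerance = 3 * 91.64 / sqrt(n) / 482.24)
  expect_equal(sd(p20$weight_g), 26.38, tolerance = 0.05)
  expect_equal(sd(p28$weight_g), 91.64, tolerance = 0.05)
  # interpolated age sits between the anchors
  p24 <- sample_population(n, 24, g, seed = 2)
  expect_gt(mean(p24$weight_g), mean(p20$weight_g))
  expect_lt(mean(p24$weight_g), mean(p28$weight_g))
})

test_that("population obeys allometry, positivity, and determinism", {
  g <- growth_model()
  p <- sample_population(500, c(20, 22, 24, 26, 28), g, seed = 3)
  expect_equal(p$weight_g, g$allometric_a * p$length_cm^3, tolerance = 1e-12)
  expect_true(all(p$weight_g > 0))
  expect_true(all(p$length_cm > p$width_cm))
  expect_identical(p, sample_population(500, c(20, 22, 24, 26, 28), g, seed = 3))
  expect_equal(nrow(sample_population(0, 20, g, seed = 1)), 0L)
  expect_error(sample_population(5, 19, g, seed = 1), "anchor span")
  expect_error(sample_population(5, 30, g, seed = 1), "anchor span")
})

test_that("observation projects size by the pinhole law", {
  cam <- camera_model(focal_px = 1000, depth_min_cm = 5, depth_max_cm = 60)
  fish <- data.frame(fish_id = "f", age_weeks = 24L, length_cm = 25,
                     width_cm = 9.5, weight_g = 325)
  o50 <- observe(fish, cam, 50, pixel_noise_sd = 0)
  expect_equal(o50$length_px, 25 * 1000 / 50)  # 500
  expect_equal(o50$width_px, 9.5 * 1000 / 50)
  # doubling depth halves the projection
  cam_wide <- camera_model(focal_px = 1000, depth_min_cm = 5, depth_max_cm = 120)
  o100 <- observe(fish, cam_wide, 100, pixel_noise_sd = 0)
  expect_equal(o100$length_px, o50$length_px / 2)
  # monotone decreasing in depth at zero noise
  px <- vapply(seq(20, 60, by = 5), function(dep)
    observe(fish, cam, dep, pixel_noise_sd = 0)$length_px, numeric(1))
  expect_true(all(diff(px) < 0))
})

test_that("depth labels quantize to the nearest 10-cm marker", {
  cam <- camera_model(focal_px = 1000, depth_min_cm = 5, depth_max_cm = 60)
  fish <- data.frame(fish_id = "f", age_weeks = 24L, length_cm = 25,
                     width_cm = 9.5, weight_g = 325)
  expect_equal(observe(fish, cam, 27, pixel_noise_sd = 0)$depth_label_cm, 30)
  expect_equal(observe(fish, cam, 44.9, pixel_noise_sd = 0)$depth_label_cm, 40)
  # labels stay on markers inside the depth range even at the edges
  expect_equal(observe(fish, cam, 58, pixel_noise_sd = 0)$depth_label_cm, 60)
  small <- data.frame(fish_id = "s", age_weeks = 20L, length_cm = 8,
                      width_cm = 3, weight_g = 50)
  expect_equal(observe(small, cam, 5, pixel_noise_sd = 0)$depth_label_cm, 10)
})

test_that("observation errors are classed and informative", {
  cam <- camera_model(focal_px = 1000, depth_min_cm = 5, depth_max_cm = 60)
  fish <- data.frame(fish_id = "f", age_weeks = 24L, length_cm = 25,
                     width_cm = 9.5, weight_g = 325)
  expect_error(observe(fish, cam, 80, pixel_noise_sd = 0), "bounds")
  # too close: projection wider than the frame is signalled, not dropped
  expect_error(observe(fish, cam, 6, pixel_noise_sd = 0),
               class = "aquaweight_projection_overflow")
})

test_that("file dataset has complete rows, correct schema, determinism", {
  cols <- c("fish_id", "age_weeks", "length_px", "width_px",
            "depth_true_cm", "depth_label_cm", "length_cm", "width_cm",
            "weight_g")
  d <- make_file_dataset(2777, seed = 7)
  expect_identical(names(d), cols)
  expect_equal(nrow(d), 2777)
  expect_true(all(d$length_px > d$width_px))
  expect_true(all(d$weight_g > 0 & d$length_cm > d$width_cm))
  expect_true(all(d$depth_label_cm %% camera_model()$marker_spacing_cm == 0))
  expect_true(all(d$depth_true_cm >= 5 & d$depth_true_cm <= 60))
  # projected sizes always fit the frame
  expect_true(all(d$length_px <= camera_model()$image_width_px))
  expect_identical(d, make_file_dataset(2777, seed = 7))
  expect_equal(nrow(make_file_dataset(1, seed = 1)), 1L)
  expect_equal(nrow(make_file_dataset(0)), 0L)
})

test_that("CSV round-trip of the file dataset preserves the table", {
  d <- make_file_dataset(50, seed = 9)
  tmp <- tempfile(fileext = ".csv")
  write.csv(d, tmp, row.names = FALSE)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$weight_g, d$weight_g, tolerance = 1e-6)
  expect_identical(names(back), names(d))
})
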