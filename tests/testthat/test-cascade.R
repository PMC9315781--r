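# Fast fixed hyperparameters: skip the SVR grid search where the test is
# about cascade mechanics rather than model selection.
fast_grids <- list(depth = list(cost = 10, gamma = 0.1, epsilon = 0.1))

test_that("cascade validates its input schema", {
  d <- make_file_dataset(60, seed = 1)
  expect_error(fish_cascade(d[, -which(names(d) == "weight_g")]),
               "weight_g")
  expect_error(fish_cascade(d, depth_col = "nope"), "nope")
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 2))
  expect_error(predict(m, data.frame(age_weeks = 20)), "length_px")
})

test_that("a trained cascade predicts coherently and deterministically", {
  d <- make_file_dataset(400, seed = 3)
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 4))
  expect_s3_class(m, "fish_cascade")
  nd <- d[1:5, c("age_weeks", "length_px", "width_px")]
  p <- predict(m, nd)
  expect_equal(names(p), c("depth_est_cm", "length_est_cm", "width_est_cm",
                           "weight_est_g"))
  expect_equal(nrow(p), 5L)
  # empty stream and statelessness
  expect_equal(nrow(predict(m, nd[0, ])), 0L)
  two <- predict(m, nd[c(1, 1), ])
  expect_equal(unlist(two[1, ]), unlist(two[2, ]))
  # retraining with the same seed reproduces residual summaries
  m2 <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 4))
  expect_equal(m$residual_summaries$depth$mae, m2$residual_summaries$depth$mae)
  expect_equal(predict(m2, nd), p)
})

test_that("tiny tables train with a warning rather than failing", {
  d <- make_file_dataset(8, seed = 5)
  w <- capture_warnings(m <- fish_cascade(d, grids = fast_grids, seed = 6))
  expect_true(any(grepl("small training table", w)))
  expect_s3_class(m, "fish_cascade")
  expect_equal(nrow(predict(m, d[, c("age_weeks", "length_px", "width_px")])),
               8L)
})

test_that("noiseless synthetic data gives near-perfect depth recovery", {
  cam <- small_camera()
  d <- make_file_dataset(800, camera = cam, pixel_noise_sd = 0,
                         quantize = FALSE, seed = 7)
  m <- suppressWarnings(fish_cascade(d, seed = 8))
  ev <- evaluate_cascade(m)
  expect_gte(ev$depth$r2, 0.95)
})

test_that("weight stage is monotone in body size at fixed age and depth", {
  d <- make_file_dataset(600, seed = 9)
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 10))
  # hold age and depth fixed and grow the fish: the linear weight stage
  # must never assign a smaller weight to a larger fish
  depth <- 40
  len_px <- seq(400, 700, by = 25)
  x3 <- cbind(age_weeks = 24, length_px = len_px, width_px = 0.38 * len_px,
              depth_cm = depth,
              length_cm = len_px * depth / camera_model()$focal_px,
              width_cm = 0.38 * len_px * depth / camera_model()$focal_px)
  w <- predict(m$stages$weight, x3)
  expect_true(all(diff(w) > -1e-8))
})

test_that("cascade persistence round-trips predictions exactly", {
  d <- make_file_dataset(150, seed = 11)
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 12))
  tmp <- tempfile(fileext = ".rds")
  save_cascade(m, tmp)
  m2 <- load_cascade(tmp)
  nd <- d[1:10, c("age_weeks", "length_px", "width_px")]
  expect_identical(predict(m, nd), predict(m2, nd))
  saveRDS(list(format = "other"), tmp)
  expect_error(load_cascade(tmp), "archive")
})

test_that("evaluate_cascade reports all four outputs with sane values", {
  d <- make_file_dataset(500, seed = 13)
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 14))
  ev <- evaluate_cascade(m)
  expect_named(ev, c("depth", "length", "width", "weight"))
  for (r in ev) {
    expect_s3_class(r, "metrics_report")
    expect_gte(r$mae, 0)
    expect_lte(r$r2, 1)
  }
  # perfect predictions degenerate case
  perfect <- metrics_report(d$weight_g, d$weight_g)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
})

test_that("summary, coef, residuals, and print methods work", {
  d <- make_file_dataset(300, seed = 15)
  m <- suppressWarnings(fish_cascade(d, grids = fast_grids, seed = 16))
  expect_output(print(m), "depth = SVR")
  s <- summary(m)
  expect_output(print(s), "Test performance")
  cf <- coef(m)
  expect_null(cf$depth)            # SVR has no linear coefficients
  expect_length(cf$weight, 7)      # intercept + six features
  r <- residuals(m)
  expect_equal(nrow(r), length(m$split$test))
  expect_named(r, c("depth", "length", "width", "weight"))
})
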