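test_that("bbox size extraction reads extents and flags vertical fish", {
  s <- bbox_to_size(c(x_min = 10, y_min = 20, x_max = 110, y_max = 60))
  expect_equal(s$length_px, 100)
  expect_equal(s$width_px, 40)
  expect_false(s$swapped)
  sq <- bbox_to_size(c(0, 0, 50, 50))
  expect_equal(c(sq$length_px, sq$width_px), c(50, 50))
  v <- bbox_to_size(c(0, 0, 40, 90))
  expect_equal(c(v$length_px, v$width_px), c(90, 40))
  expect_true(v$swapped)
  expect_error(bbox_to_size(c(0, 0, 0, 10)), "degenerate")
})

test_that("score filter keeps >= threshold, preserving order", {
  d <- data.frame(x_min = 0, y_min = 0, x_max = 1, y_max = 1,
                  score = c(0.9, 0.5, 0.8, 0.79))
  kept <- filter_by_score(d, 0.8)
  expect_equal(kept$score, c(0.9, 0.8))  # 0.8 itself passes
  expect_equal(nrow(filter_by_score(d[0, ], 0.8)), 0L)
  expect_error(filter_by_score(d, 1.5))
})

test_that("iou matches hand-computed and rasterized values", {
  b <- c(0, 0, 2, 2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, c(5, 5, 7, 7)), 0)
  expect_equal(iou(b, c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(b, c(2, 0, 4, 2)), 0)  # touching edges do not overlap
  # symmetry + rasterization oracle on random integer boxes <= 20 px
  set.seed(11)
  for (i in 1:50) {
    b1 <- c(sort(sample(0:20, 2)), sort(sample(0:20, 2)))[c(1, 3, 2, 4)]
    b2 <- c(sort(sample(0:20, 2)), sort(sample(0:20, 2)))[c(1, 3, 2, 4)]
    if (b1[1] == b1[3] || b1[2] == b1[4] || b2[1] == b2[3] || b2[2] == b2[4]) next
    expect_equal(iou(b1, b2), iou(b2, b1))
    expect_equal(iou(b1, b2), iou_raster(b1, b2), tolerance = 1e-12)
    expect_gte(iou(b1, b2), 0); expect_lte(iou(b1, b2), 1)
  }
})

test_that("average precision handles exact, missing, and noisy detections", {
  gts <- data.frame(x_min = c(0, 100), y_min = c(0, 100),
                    x_max = c(50, 160), y_max = c(40, 140))
  exact <- cbind(gts, score = c(0.99, 0.99))
  expect_equal(average_precision(exact, gts, 0.5), 1)
  expect_equal(unname(ap_summary(exact, gts)), c(100, 100, 100))
  expect_equal(average_precision(gts[0, ], gts, 0.5), 0)
  expect_equal(average_precision(NULL, NULL, 0.5), 1)  # vacuous convention
  expect_equal(average_precision(exact, gts[0, ], 0.5), 0)
  # one TP above a far FP in score: AP50 still 1 under 101-pt interpolation
  one_gt <- gts[1, ]
  dets <- data.frame(x_min = c(0, 500), y_min = c(0, 500),
                     x_max = c(50, 520), y_max = c(40, 520),
                     score = c(0.9, 0.8))
  expect_equal(average_precision(dets, one_gt, 0.5), 1)
  # FP outranking the TP halves the score
  dets2 <- dets; dets2$score <- c(0.8, 0.9)
  expect_lt(average_precision(dets2, one_gt, 0.5),
            average_precision(dets, one_gt, 0.5))
  # order invariance: AP sorts by score internally
  expect_equal(average_precision(dets[2:1, ], one_gt, 0.5), 1)
})

test_that("adding a top-scoring false positive never raises AP", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    gts <- data.frame(x_min = seq(0, by = 60, length.out = n), y_min = 0,
                      x_max = seq(40, by = 60, length.out = n), y_max = 30)
    dets <- cbind(gts, score = runif(n, 0.5, 0.9))
    fp <- data.frame(x_min = 1000, y_min = 1000, x_max = 1020, y_max = 1020,
                     score = 0.99)
    expect_lte(average_precision(rbind(dets, fp), gts, 0.5),
               average_precision(dets, gts, 0.5))
  }
})

test_that("losses take their closed-form values and vanish at truth", {
  expect_equal(class_loss(1), 0)
  expect_equal(class_loss(0.5), log(2))
  expect_equal(class_loss(exp(-1)), 1)
  expect_error(class_loss(0), "must be in")

  expect_equal(bbox_loss(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(bbox_loss(c(0.5, 0, 0, 0), c(0, 0, 0, 0)), 0.125)
  expect_equal(bbox_loss(c(2, 0, 0, 0), c(0, 0, 0, 0)), 1.5)
  # smooth-L1 is continuous at |x| = 1
  expect_equal(smooth_l1(1), 0.5)
  expect_equal(smooth_l1(1 - 1e-9), 0.5, tolerance = 1e-6)

  m <- matrix(c(1, 0, 1, 1), 2, 2)
  eps <- 1e-9
  p_true <- abs(m - eps)
  expect_lt(mask_loss(p_true, m), 1e-6)
  expect_equal(mask_loss(matrix(0.5, 2, 2), m), log(2))
  expect_equal(mask_loss(matrix(exp(-1), 1, 1), matrix(1, 1, 1)), 1)
  expect_error(mask_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")

  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(0.1, 0.2, 0.3), 0.6)
  expect_equal(total_loss(1, 2, 3, weights = c(1, 0.5, 0)), 2)
  expect_error(total_loss(-1, 0, 0), "nonnegative")
})

test_that("oracle detector reproduces annotations and AP 1 on any scene", {
  cam <- small_camera()
  set.seed(31)
  for (k in 1:5) {
    n_fish <- sample(0:4, 1)
    obs <- if (n_fish > 0) {
      pop <- sample_population(n_fish, c(20, 24, 28), seed = 40 + k)
      do.call(rbind, lapply(seq_len(n_fish), function(i)
        observe(pop[i, ], cam, runif(1, 30, 55), pixel_noise_sd = 0)))
    } else NULL
    sc <- render_scene(obs, cam, turbidity = runif(1, 0, 0.8), seed = 50 + k)
    dets <- detect_oracle(sc)
    expect_equal(nrow(dets), n_fish)
    if (n_fish > 0) {
      expect_equal(dets$x_min, as.numeric(sc$annotations$x_min))
      expect_equal(unname(ap_summary(dets, sc$annotations)["AP"]), 100)
    }
  }
})

test_that("threshold detector recovers a clear single fish and stays quiet on empty scenes", {
  cam <- small_camera()
  pop <- sample_population(1, 24, seed = 61)
  ob <- observe(pop[1, ], cam, 40, pixel_noise_sd = 0)
  sc <- render_scene(ob, cam, turbidity = 0, seed = 62)
  dets <- detect_threshold(sc)
  expect_equal(nrow(dets), 1L)
  expect_gte(iou(dets[1, ], sc$annotations[1, ]), 0.5)
  expect_gte(dets$score[1], 0.8)  # clean ellipse passes the pipeline filter
  empty <- render_scene(NULL, cam, turbidity = 0, seed = 63)
  expect_equal(nrow(detect_threshold(empty)), 0L)
})

test_that("detection tables round-trip through CSV", {
  d <- data.frame(x_min = c(1.5, 7), y_min = c(2, 3), x_max = c(10, 20),
                  y_max = c(12, 13), score = c(0.91, 0.85))
  tmp <- tempfile(fileext = ".csv")
  write_detections(d, tmp, image_id = "frame_01")
  back <- read_detections(tmp)
  expect_equal(back$x_min, d$x_min)
  expect_equal(back$score, d$score)
  expect_equal(unique(back$image_id), "frame_01")
})
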