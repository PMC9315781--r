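test_that("scenes record exact annotations independent of turbidity", {
  cam <- small_camera()
  obs <- data.frame(fish_id = "f1", age_weeks = 22L, length_px = 80,
                    width_px = 30, depth_label_cm = 30)
  sc <- render_scene(obs, cam, turbidity = 0, seed = 1)
  expect_s3_class(sc, "aqw_scene")
  ann <- sc$annotations
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$x_max - ann$x_min, 80)  # bbox width = round(length_px)
  expect_equal(ann$y_max - ann$y_min, 30)
  expect_true(ann$x_min >= 0 && ann$x_max <= cam$image_width_px)
  expect_true(ann$y_min >= 0 && ann$y_max <= cam$image_height_px)
  # same seed, different turbidity: identical annotations, different pixels
  sct <- render_scene(obs, cam, turbidity = 0.8, seed = 1)
  expect_identical(sct$annotations, ann)
  expect_false(identical(sct$image, sc$image))
  # determinism: identical seed reproduces the scene byte for byte
  expect_identical(render_scene(obs, cam, 0.8, seed = 1)$image, sct$image)
  # image validity
  expect_true(all(sc$image >= 0 & sc$image <= 255 & sc$image == floor(sc$image)))
})

test_that("overlapping fish are all annotated", {
  cam <- camera_model(focal_px = 200, image_width_px = 120,
                      image_height_px = 80, depth_min_cm = 20,
                      depth_max_cm = 60)
  obs <- data.frame(fish_id = c("a", "b", "c"), age_weeks = 24L,
                    length_px = c(70, 75, 72), width_px = c(26, 28, 27),
                    depth_label_cm = 30)
  sc <- render_scene(obs, cam, 0, seed = 2)
  expect_equal(nrow(sc$annotations), 3L)
  ious <- c(iou(sc$annotations[1, ], sc$annotations[2, ]),
            iou(sc$annotations[1, ], sc$annotations[3, ]),
            iou(sc$annotations[2, ], sc$annotations[3, ]))
  expect_gt(max(ious), 0)  # the small frame forces some overlap
})

test_that("empty scenes render background only", {
  sc <- render_scene(NULL, small_camera(), 0.5, seed = 3)
  expect_equal(nrow(sc$annotations), 0L)
  expect_equal(dim(sc$image), c(180, 320, 3))
})

test_that("scene PNG + VIA annotation round-trip preserves geometry", {
  cam <- small_camera()
  obs <- data.frame(fish_id = c("f1", "f2"), age_weeks = c(22L, 26L),
                    length_px = c(80, 60), width_px = c(30, 23),
                    depth_label_cm = c(30, 40))
  sc <- render_scene(obs, cam, 0.3, seed = 4)
  img_path <- tempfile(fileext = ".png")
  ann_path <- tempfile(fileext = ".json")
  write_scene_png(sc, img_path, ann_path)
  img <- read_frame_png(img_path)
  expect_equal(img, sc$image * 1)  # PNG round-trip is exact for 8-bit data
  back <- read_via_annotations(ann_path)
  expect_equal(back$x_min, as.numeric(sc$annotations$x_min))
  expect_equal(back$x_max, as.numeric(sc$annotations$x_max))
  expect_equal(back$age_weeks, as.numeric(sc$annotations$age_weeks))
  expect_equal(back$depth_cm, as.numeric(sc$annotations$depth_label_cm))
  expect_equal(back$fish_id, sc$annotations$fish_id)
})

test_that("VIA reader handles project dialect, polygons, unknown shapes", {
  doc <- list(
    "_via_img_metadata" = list(
      "img1.png" = list(filename = "img1.png", regions = list(
        list(shape_attributes = list(name = "rect", x = 10, y = 20,
                                     width = 100, height = 40),
             region_attributes = list(age_weeks = "24", depth_cm = "30")),
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = list(0, 10, 0),
                                     all_points_y = list(0, 0, 6)),
             region_attributes = list()),
        list(shape_attributes = list(name = "circle", cx = 5, cy = 5, r = 2),
             region_attributes = list())))))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  expect_warning(ann <- read_via_annotations(tmp), "unknown shape")
  expect_equal(nrow(ann), 2L)
  expect_equal(unlist(ann[1, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(10, 20, 110, 60))
  expect_equal(ann$age_weeks[1], 24)
  expect_equal(unlist(ann[2, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(0, 0, 10, 6))
  # malformed JSON errors with the file named
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_via_annotations(bad), "malformed JSON")
  # empty region list
  empty <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = list(filename = "a.png", regions = list())),
                       empty, auto_unbox = TRUE)
  expect_equal(nrow(read_via_annotations(empty)), 0L)
})

test_that("results writer produces the documented schema and round-trips", {
  rows <- data.frame(fish_id = c("a", "b"), age_weeks = c(22, 26),
                     length_px = c(512.3456789, 301.2), width_px = c(194.7, 115.3),
                     depth_est_cm = c(31.2, 44.8), length_est_cm = c(25.61, 21.08),
                     width_est_cm = c(9.73, 8.01), weight_est_g = c(352.447, 201.993))
  tmp <- tempfile(fileext = ".csv")
  write_results(rows, tmp)
  back <- read_results(tmp)
  expect_equal(names(back), names(rows))
  expect_equal(back$weight_est_g, signif(rows$weight_est_g, 6))
  # header-only output for zero rows
  write_results(rows[0, ], tmp)
  expect_equal(nrow(read_results(tmp)), 0L)
  expect_error(write_results(rows[, -8], tmp), "weight_est_g")
  if (!requireNamespace("openxlsx", quietly = TRUE))
    expect_error(write_results(rows, tempfile(fileext = ".xlsx"),
                               format = "xlsx"), "openxlsx")
})
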