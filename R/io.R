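#' Read a VIA-style annotation JSON file
#'
#' Accepts both dialects emitted by the VGG Image Annotator: a full
#' project file (regions under `_via_img_metadata`) or the bare
#' filename-keyed region-list export. Rectangles `(x, y, width, height)`
#' map to boxes `(x, y, x + width, y + height)`; polygons are reduced to
#' their axis-aligned bounding rectangle (the pipeline only consumes
#' boxes). Region attributes `age_weeks`, `depth_cm`, and `fish_id` are
#' coerced to numbers/strings when present. Unknown shape types are
#' skipped with a warning. All coordinates are 0-based, half-open.
#'
#' @param path path to the JSON file.
#' @return data.frame with columns `filename`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `age_weeks`, `depth_cm`, `fish_id`.
#' @export
read_via_annotations <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed JSON in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  rows <- list()
  for (img in doc) {
    fname <- img$filename %||% ""
    for (reg in (img$regions %||% list())) {
      sa <- reg$shape_attributes
      ra <- reg$region_attributes %||% list()
      box <- switch(sa$name %||% "missing",
        rect = {
          if ((sa$width %||% 0) <= 0 || (sa$height %||% 0) <= 0) {
            warning("skipping rect with nonpositive size in ", fname)
            NULL
          } else c(sa$x, sa$y, sa$x + sa$width, sa$y + sa$height)
        },
        polygon = , polyline = {
          xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
          c(min(xs), min(ys), max(xs), max(ys))
        },
        {
          warning("skipping unknown shape type '", sa$name %||% "?",
                  "' in ", fname)
          NULL
        })
      if (is.null(box)) next
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fname,
        x_min = as.numeric(box[1]), y_min = as.numeric(box[2]),
        x_max = as.numeric(box[3]), y_max = as.numeric(box[4]),
        age_weeks = as.numeric(ra$age_weeks %||% NA),
        depth_cm = as.numeric(ra$depth_cm %||% NA),
        fish_id = as.character(ra$fish_id %||% NA),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(filename = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), age_weeks = numeric(),
                      depth_cm = numeric(), fish_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write scene annotations as a VIA-style region-list JSON
#'
#' @param annotations data.frame with `x_min`, `y_min`, `x_max`, `y_max`
#'   and optionally `age_weeks`, `depth_label_cm` (or `depth_cm`),
#'   `fish_id`.
#' @param path output JSON path.
#' @param filename image filename recorded in the annotation entry.
#' @return `path`, invisibly.
#' @export
write_via_annotations <- function(annotations, path, filename = "scene.png") {
  depth <- annotations$depth_label_cm %||% annotations$depth_cm
  regions <- lapply(seq_len(nrow(annotations)), function(i) {
    list(shape_attributes = list(
           name = "rect",
           x = annotations$x_min[i], y = annotations$y_min[i],
           width = annotations$x_max[i] - annotations$x_min[i],
           height = annotations$y_max[i] - annotations$y_min[i]),
         region_attributes = list(
           age_weeks = annotations$age_weeks[i] %||% NA,
           depth_cm = if (is.null(depth)) NA else depth[i],
           fish_id = annotations$fish_id[i] %||% NA))
  })
  doc <- stats::setNames(list(list(filename = filename, regions = regions)),
                         filename)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

results_columns <- c("fish_id", "age_weeks", "length_px", "width_px",
                     "depth_est_cm", "length_est_cm", "width_est_cm",
                     "weight_est_g")

#' Write per-fish estimation results
#'
#' CSV is the canonical format (one header row, 6 significant digits, so
#' a write/read round-trip is lossless at that precision); XLSX export
#' (one worksheet named "estimates") is available when the openxlsx
#' package is installed.
#'
#' @param rows data.frame of per-fish estimates with columns `fish_id`,
#'   `age_weeks`, `length_px`, `width_px`, `depth_est_cm`,
#'   `length_est_cm`, `width_est_cm`, `weight_est_g`. Zero rows write a
#'   header-only file.
#' @param path output file path.
#' @param format `"csv"` or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  missing_cols <- setdiff(results_columns, names(rows))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- rows[, results_columns, drop = FALSE]
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 6)
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE)
  } else {
    if (!requireNamespace("openxlsx", quietly = TRUE))
      stop("xlsx export requires the 'openxlsx' package; ",
           "use format = \"csv\" instead", call. = FALSE)
    wb <- openxlsx::createWorkbook()
    openxlsx::addWorksheet(wb, "estimates")
    openxlsx::writeData(wb, "estimates", rows)
    openxlsx::saveWorkbook(wb, path, overwrite = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read/write detection tables
#'
#' Detections travel as CSV with columns `image_id`, `x_min`, `y_min`,
#' `x_max`, `y_max`, `score`.
#'
#' @param dets data.frame of detections; an `image_id` column is added
#'   (value `image_id` argument) when absent.
#' @param path CSV path.
#' @param image_id identifier used when `dets` lacks the column.
#' @return `write_detections()`: `path` invisibly; `read_detections()`:
#'   the detections data.frame.
#' @export
write_detections <- function(dets, path, image_id = 1L) {
  if (!"image_id" %in% names(dets))
    dets <- cbind(image_id = rep(image_id, nrow(dets)), dets)
  write.csv(dets[, c("image_id", "x_min", "y_min", "x_max", "y_max",
                     "score")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
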