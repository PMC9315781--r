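#' Train / validation / test split
#'
#' Shuffles `1:n` by seed and partitions it in two levels: the outer
#' fraction separates the training phase from the test set, and the inner
#' fraction separates training proper from validation (used for grid
#' search). Sizes follow nearest-integer rounding with ties to even:
#' `|test| = n - round(n * outer)`, then of the remaining `m`,
#' `|val| = m - round(m * inner)`. With `n = 2777` and fractions
#' 0.7 / 0.8 this gives 1555 / 389 / 833; with `n = 4287` and 0.7 / 0.7,
#' 2101 / 900 / 1286 — the split sizes used for the fish file and image
#' datasets.
#'
#' @param n number of rows to split.
#' @param outer_train_frac,inner_train_frac fractions in (0, 1].
#' @param seed integer seed or `NULL` (no shuffle when `NULL`).
#' @return A list of class `aqw_split` with integer index vectors
#'   `train`, `val`, `test` (disjoint, exhaustive).
#' @examples
#' lengths(split_dataset(2777, 0.7, 0.8, seed = 1))  # 1555 389 833
#' @export
split_dataset <- function(n, outer_train_frac = 0.7, inner_train_frac = 0.8,
                          seed = NULL) {
  stopifnot(n >= 1, outer_train_frac > 0, outer_train_frac <= 1,
            inner_train_frac > 0, inner_train_frac <= 1)
  idx <- with_seed(seed, sample.int(n))
  m <- round(n * outer_train_frac)           # round(): ties to even
  n_train <- round(m * inner_train_frac)
  out <- list(train = sort(idx[seq_len(n_train)]),
              val = sort(idx[seq_len(m - n_train) + n_train]),
              test = sort(idx[seq_len(n - m) + m]))
  if (any(lengths(out) == 0L))
    warning("empty partition under the requested fractions")
  structure(out, class = "aqw_split")
}

stage_features <- list(
  depth = c("age_weeks", "length_px", "width_px"),
  size = c("age_weeks", "length_px", "width_px", "depth_cm"),
  weight = c("age_weeks", "length_px", "width_px", "depth_cm",
             "length_cm", "width_cm"))

required_columns <- c("age_weeks", "length_px", "width_px",
                      "length_cm", "width_cm", "weight_g")

#' Fit the three-stage fish weight-estimation cascade
#'
#' Trains the chained model stack at the heart of the pipeline:
#' 1. **Depth stage** — camera-to-fish depth from (age, length in px,
#'    width in px); SVR by default.
#' 2. **Size stage** — length and width in centimetres from the same
#'    features plus depth, as two independently trained single-target
#'    regressors; linear regression by default.
#' 3. **Weight stage** — weight in grams from all of the above plus the
#'    centimetre dimensions; linear regression by default.
#'
#' Stages are trained on annotated values (the measured depth label and
#' studio-measured centimetre dimensions); at prediction time each
#' stage's output feeds the next, so only age and pixel dimensions are
#' needed. Families with a hyperparameter grid (by default only SVR) are
#' tuned by [grid_search()] on the validation split; held-out residual
#' statistics per stage are kept on the fitted object.
#'
#' @param data data.frame with columns `age_weeks`, `length_px`,
#'   `width_px`, `length_cm`, `width_cm`, `weight_g`, and the depth
#'   column named by `depth_col`.
#' @param families named character vector giving the regression family of
#'   each stage, e.g. `c(depth = "svr", size = "lr", weight = "lr")`
#'   (the configuration selected for the real fish data).
#' @param grids named list of hyperparameter grids per stage; `NULL`
#'   entries fall back to [default_grid()] of the stage's family. Set a
#'   stage to an empty list to skip tuning and use family defaults.
#' @param outer_train_frac,inner_train_frac split fractions, see
#'   [split_dataset()].
#' @param depth_col which depth column to train on: `"depth_label_cm"`
#'   (marker-quantized annotations, the realistic default) or
#'   `"depth_true_cm"` for noiseless recovery experiments.
#' @param seed integer seed controlling the split and any stochastic
#'   fitting.
#' @return An object of class `fish_cascade` with components `stages`
#'   (fitted regressors `depth`, `length`, `width`, `weight`), `specs`,
#'   `residual_summaries`, `split`, `data`, `families`, `depth_col`.
#' @seealso [predict.fish_cascade()], [evaluate_cascade()],
#'   [cascade_case_grid()]
#' @examples
#' d <- make_file_dataset(300, seed = 1)
#' m <- fish_cascade(d, grids = list(depth = list(cost = 10, gamma = 0.1,
#'                                                epsilon = 0.1)), seed = 1)
#' head(predict(m, d[1:3, c("age_weeks", "length_px", "width_px")]))
#' @export
fish_cascade <- function(data,
                         families = c(depth = "svr", size = "lr",
                                      weight = "lr"),
                         grids = NULL,
                         outer_train_frac = 0.7, inner_train_frac = 0.8,
                         depth_col = "depth_label_cm", seed = NULL) {
  need <- c(required_columns, depth_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  families <- vapply(families, tolower, character(1))
  stopifnot(all(c("depth", "size", "weight") %in% names(families)),
            all(families %in% c("lr", "rfr", "svr")))
  n <- nrow(data)
  if (n < 10L) warning("very small training table (n = ", n,
                       "); estimates will be unstable")
  split <- split_dataset(n, outer_train_frac, inner_train_frac, seed = seed)
  df <- data
  df$depth_cm <- df[[depth_col]]
  tr <- df[split$train, , drop = FALSE]
  va <- df[split$val, , drop = FALSE]

  targets <- c(depth = "depth_cm", length = "length_cm",
               width = "width_cm", weight = "weight_g")
  stage_of <- c(depth = "depth", length = "size", width = "size",
                weight = "weight")
  stages <- list(); specs <- list(); resid <- list()
  for (out_name in names(targets)) {
    st <- stage_of[[out_name]]
    fam <- families[[st]]
    feats <- stage_features[[st]]
    x_tr <- as.matrix(tr[, feats, drop = FALSE])
    y_tr <- tr[[targets[[out_name]]]]
    grid <- if (!is.null(grids) && st %in% names(grids)) grids[[st]]
            else default_grid(fam)
    if (!is.null(grid) && length(grid) > 0 && nrow(va) > 0) {
      gs <- grid_search(fam, grid,
                        x_tr, y_tr,
                        as.matrix(va[, feats, drop = FALSE]),
                        va[[targets[[out_name]]]],
                        seed = seed)
      spec <- gs$spec
    } else {
      if (!is.null(grid) && length(grid) > 0 && nrow(va) == 0)
        warning("no validation rows; skipping grid search for the ",
                st, " stage")
      spec <- regressor_spec(fam)
    }
    fit <- with_seed(seed, fit_regressor(spec, x_tr, y_tr))
    stages[[out_name]] <- fit
    specs[[out_name]] <- spec
    if (nrow(va) > 1) {
      pv <- predict(fit, as.matrix(va[, feats, drop = FALSE]))
      resid[[out_name]] <- metrics_report(va[[targets[[out_name]]]], pv,
                                          label = out_name)
    }
  }
  structure(list(stages = stages, specs = specs,
                 residual_summaries = resid, split = split, data = data,
                 families = families, depth_col = depth_col, seed = seed),
            class = "fish_cascade")
}

#' Predict depth, size, and weight for detected fish
#'
#' Runs the fitted cascade forward: the depth stage's estimate feeds the
#' size stage, whose centimetre estimates feed the weight stage, so a
#' prediction needs only the user-supplied age and the detector's pixel
#' dimensions.
#'
#' @param object a [fish_cascade()].
#' @param newdata data.frame with `age_weeks`, `length_px`, `width_px`
#'   (extra columns ignored). Zero rows allowed.
#' @param ... unused.
#' @return data.frame with `depth_est_cm`, `length_est_cm`,
#'   `width_est_cm`, `weight_est_g`, one row per input row.
#' @export
predict.fish_cascade <- function(object, newdata, ...) {
  if (is.null(object$stages))
    stop("cascade has no fitted stages", call. = FALSE)
  need <- c("age_weeks", "length_px", "width_px")
  missing_cols <- setdiff(need, names(newdata))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data.frame(depth_est_cm = numeric(0), length_est_cm = numeric(0),
                    width_est_cm = numeric(0), weight_est_g = numeric(0))
  if (nrow(newdata) == 0L) return(out)
  x1 <- as.matrix(newdata[, stage_features$depth, drop = FALSE])
  depth <- predict(object$stages$depth, x1)
  x2 <- cbind(x1, depth_cm = depth)
  len <- predict(object$stages$length, x2)
  wid <- predict(object$stages$width, x2)
  x3 <- cbind(x2, length_cm = len, width_cm = wid)
  w <- predict(object$stages$weight, x3)
  data.frame(depth_est_cm = depth, length_est_cm = len,
             width_est_cm = wid, weight_est_g = w)
}

#' Evaluate a fitted cascade on held-out data
#'
#' Chains predictions on the evaluation rows (by default the cascade's
#' own test split) and reports MAE, R-squared, MAE ratio, and signed
#' error statistics for each output: depth against the trained depth
#' column, centimetre length and width against the annotated dimensions,
#' and weight against the true weight.
#'
#' @param model a [fish_cascade()].
#' @param data evaluation rows with the same columns as the training
#'   table; defaults to the model's test split.
#' @return Named list of [metrics_report()] objects: `depth`, `length`,
#'   `width`, `weight`.
#' @export
evaluate_cascade <- function(model, data = NULL) {
  stopifnot(inherits(model, "fish_cascade"))
  if (is.null(data)) data <- model$data[model$split$test, , drop = FALSE]
  preds <- predict(model, data)
  list(depth = metrics_report(data[[model$depth_col]], preds$depth_est_cm,
                              label = "depth (cm)"),
       length = metrics_report(data$length_cm, preds$length_est_cm,
                               label = "length (cm)"),
       width = metrics_report(data$width_cm, preds$width_est_cm,
                              label = "width (cm)"),
       weight = metrics_report(data$weight_g, preds$weight_est_g,
                               label = "weight (g)"))
}

#' Nine-case comparison of size/weight regression families
#'
#' Reproduces the experiment-design grid used to choose the cascade's
#' regression families: depth is always estimated by SVR, while the size
#' and weight stages each try SVR, RFR, and LR. Labels are three-letter
#' codes (depth, size, weight family initials), so `"SLL"` is the
#' SVR/LR/LR configuration. Because every stage trains on annotated
#' values, the three size and three weight stages are fitted once each
#' and the nine chains are evaluated on the shared test split.
#'
#' @inheritParams fish_cascade
#' @return data.frame with one row per case (`SSL`, `SSR`, `SSS`, `SRL`,
#'   `SRR`, `SRS`, `SLL`, `SLR`, `SLS`) and columns `label`, `mae`, `r2`,
#'   `mae_ratio`, `mean_error`, `sd_error`, `n` for the weight output.
#' @export
cascade_case_grid <- function(data, grids = NULL,
                              outer_train_frac = 0.7,
                              inner_train_frac = 0.8,
                              depth_col = "depth_label_cm", seed = NULL) {
  size_fams <- c(S = "svr", R = "rfr", L = "lr")
  weight_fams <- c(L = "lr", R = "rfr", S = "svr")
  # fit one full cascade per size family; reuse its depth stage
  base <- list()
  for (sf in names(size_fams)) {
    fams <- c(depth = "svr", size = size_fams[[sf]], weight = "lr")
    base[[sf]] <- fish_cascade(data, families = fams, grids = grids,
                               outer_train_frac = outer_train_frac,
                               inner_train_frac = inner_train_frac,
                               depth_col = depth_col, seed = seed)
  }
  # fit the three weight-stage regressors once, on annotated features
  m0 <- base[["S"]]
  df <- data; df$depth_cm <- df[[depth_col]]
  tr <- df[m0$split$train, , drop = FALSE]
  x_tr <- as.matrix(tr[, stage_features$weight, drop = FALSE])
  weight_fits <- lapply(weight_fams, function(fam) {
    grid <- if (!is.null(grids) && "weight" %in% names(grids))
      grids$weight else default_grid(fam)
    va <- df[m0$split$val, , drop = FALSE]
    spec <- if (!is.null(grid) && length(grid) > 0 && nrow(va) > 0)
      grid_search(fam, grid, x_tr, tr$weight_g,
                  as.matrix(va[, stage_features$weight, drop = FALSE]),
                  va$weight_g, seed = seed)$spec
    else regressor_spec(fam)
    with_seed(seed, fit_regressor(spec, x_tr, tr$weight_g))
  })
  te <- df[m0$split$test, , drop = FALSE]
  rows <- list()
  for (sf in names(size_fams)) {
    m <- base[[sf]]
    p <- predict(m, te)
    x3 <- cbind(as.matrix(te[, stage_features$depth, drop = FALSE]),
                depth_cm = p$depth_est_cm, length_cm = p$length_est_cm,
                width_cm = p$width_est_cm)
    for (wf in names(weight_fams)) {
      label <- paste0("S", sf, wf)
      w <- predict(weight_fits[[wf]], x3)
      rows[[label]] <- as.data.frame(
        metrics_report(te$weight_g, w, label = label))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fish_cascade <- function(x, ...) {
  cat("Fish weight-estimation cascade\n")
  cat(sprintf("  stages: depth = %s, size = %s, weight = %s\n",
              toupper(x$families[["depth"]]), toupper(x$families[["size"]]),
              toupper(x$families[["weight"]])))
  cat(sprintf("  trained on %d rows (train %d / val %d / test %d), depth column '%s'\n",
              nrow(x$data), length(x$split$train), length(x$split$val),
              length(x$split$test), x$depth_col))
  invisible(x)
}

#' @export
summary.fish_cascade <- function(object, ...) {
  res <- list(model = object,
              validation = object$residual_summaries,
              test = evaluate_cascade(object))
  class(res) <- "summary.fish_cascade"
  res
}

#' @export
print.summary.fish_cascade <- function(x, ...) {
  print(x$model)
  cat("\nValidation residuals (annotated inputs):\n")
  for (r in x$validation) print(r)
  cat("\nTest performance (chained predictions):\n")
  for (r in x$test) print(r)
  invisible(x)
}

#' @export
coef.fish_cascade <- function(object, ...) {
  lapply(object$stages, coef)
}

#' @export
residuals.fish_cascade <- function(object, ...) {
  te <- object$data[object$split$test, , drop = FALSE]
  p <- predict(object, te)
  data.frame(depth = p$depth_est_cm - te[[object$depth_col]],
             length = p$length_est_cm - te$length_cm,
             width = p$width_est_cm - te$width_cm,
             weight = p$weight_est_g - te$weight_g)
}

#' Diagnostic plots for a fitted cascade
#'
#' Plots predicted against observed weight on the test split and a
#' histogram of the weight residuals.
#'
#' @param x a [fish_cascade()].
#' @param ... passed to [plot()].
#' @export
plot.fish_cascade <- function(x, ...) {
  te <- x$data[x$split$test, , drop = FALSE]
  p <- predict(x, te)
  old <- par(mfrow = c(1, 2)); on.exit(par(old))
  plot(te$weight_g, p$weight_est_g, xlab = "actual weight (g)",
       ylab = "estimated weight (g)", main = "Weight: test split", ...)
  abline(0, 1, lty = 2)
  hist(p$weight_est_g - te$weight_g, xlab = "error (g)",
       main = "Weight residuals")
  invisible(x)
}

#' Save / load a fitted cascade
#'
#' Persists the fitted stages, hyperparameters, scaler statistics, split,
#' and training data as a versioned archive; loading restores an object
#' that predicts identically.
#'
#' @param model a [fish_cascade()].
#' @param path file path.
#' @return `save_cascade()`: `path` invisibly. `load_cascade()`: the
#'   restored `fish_cascade`.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "fish_cascade"))
  saveRDS(list(format = "aquaweight_cascade", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "aquaweight_cascade"))
    stop("not an aquaweight cascade archive", call. = FALSE)
  obj$model
}
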