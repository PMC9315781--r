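#' Area-based fish weight estimators
#'
#' Seven closed-form estimators that map body area A (cm^2, length times
#' width times an area coefficient) to weight in grams — the classical
#' allometric baselines the regression cascade is compared against:
#'
#' * W1 power (fixed exponent): `1.70 * A^1.5`
#' * W2 power: `0.124 * A^1.55`
#' * W3 exponential: `75.505 * exp(0.008 * A)`
#' * W4 linear: `2.6609 * A - 141.14`
#' * W5 logarithmic: `448.84 * ln(A) - 1984.1`
#' * W6 quadratic: `0.0048 * A^2 + 0.9309 * A + 7.8245`
#' * W7 power: `0.2501 * A^1.3821`
#'
#' `comparator_spec()` builds one estimator; `default_comparators()`
#' returns all seven with their published coefficients.
#'
#' @param form one of `"power_fixed"`, `"power"`, `"exponential"`,
#'   `"linear"`, `"logarithmic"`, `"polynomial2"`.
#' @param coefficients ordered numeric coefficients; length must match
#'   the form's arity (2 except `polynomial2`, which takes 3 as
#'   (a, b, c) in `a A^2 + b A + c`).
#' @param area_coefficient positive scale factor inside
#'   `A = length * width * coefficient`.
#' @param label optional display label.
#' @return A list of class `comparator_spec`.
#' @export
comparator_spec <- function(form, coefficients, area_coefficient = 1,
                            label = NULL) {
  form <- match.arg(form, c("power_fixed", "power", "exponential",
                            "linear", "logarithmic", "polynomial2"))
  arity <- if (form == "polynomial2") 3L else 2L
  if (length(coefficients) != arity)
    stop(sprintf("form '%s' takes %d coefficients, got %d", form, arity,
                 length(coefficients)), call. = FALSE)
  stopifnot(area_coefficient > 0)
  structure(list(form = form, coefficients = as.numeric(coefficients),
                 area_coefficient = area_coefficient,
                 label = label %||% form),
            class = "comparator_spec")
}

#' @rdname comparator_spec
#' @export
default_comparators <- function(area_coefficient = 1) {
  list(
    W1 = comparator_spec("power_fixed", c(1.70, 1.5), area_coefficient, "W1"),
    W2 = comparator_spec("power", c(0.124, 1.55), area_coefficient, "W2"),
    W3 = comparator_spec("exponential", c(75.505, 0.008), area_coefficient, "W3"),
    W4 = comparator_spec("linear", c(2.6609, -141.14), area_coefficient, "W4"),
    W5 = comparator_spec("logarithmic", c(448.84, -1984.1), area_coefficient, "W5"),
    W6 = comparator_spec("polynomial2", c(0.0048, 0.9309, 7.8245),
                         area_coefficient, "W6"),
    W7 = comparator_spec("power", c(0.2501, 1.3821), area_coefficient, "W7"))
}

#' Body area of a fish
#'
#' `A = length * width * area_coefficient`, in cm^2.
#'
#' @param length_cm,width_cm positive dimensions in cm.
#' @param area_coefficient positive scale factor.
#' @return Area in cm^2 (vectorized).
#' @export
fish_area <- function(length_cm, width_cm, area_coefficient = 1) {
  if (any(length_cm <= 0) || any(width_cm <= 0) || area_coefficient <= 0)
    stop("dimensions and area coefficient must be positive", call. = FALSE)
  length_cm * width_cm * area_coefficient
}

#' Evaluate an area-based weight estimator
#'
#' @param spec a [comparator_spec()].
#' @param A body area in cm^2 (vectorized); must be strictly positive for
#'   the logarithmic form.
#' @return Estimated weight in grams.
#' @examples
#' area_weight(default_comparators()$W1, 100)  # 1700
#' @export
area_weight <- function(spec, A) {
  stopifnot(inherits(spec, "comparator_spec"))
  if (any(A < 0)) stop("negative area", call. = FALSE)
  k <- spec$coefficients
  switch(spec$form,
    power_fixed = ,
    power = k[1] * A^k[2],
    exponential = k[1] * exp(k[2] * A),
    linear = k[1] * A + k[2],
    logarithmic = {
      if (any(A <= 0))
        stop("logarithmic form needs strictly positive area", call. = FALSE)
      k[1] * log(A) + k[2]
    },
    polynomial2 = k[1] * A^2 + k[2] * A + k[3])
}

#' Fit an area-based estimator to (area, weight) pairs
#'
#' Linear and quadratic forms are fitted by ordinary least squares on A;
#' the logarithmic form by OLS on ln(A); the exponential by OLS of ln(W)
#' on A; and the power forms by OLS of ln(W) on ln(A) (back-transformed).
#' The log-space fits are exact on noiseless data from their own family;
#' on noisy data they differ from nonlinear least squares, which is
#' deliberate — they are simple and deterministic.
#'
#' @param form estimator family, as in [comparator_spec()].
#' @param A,W paired areas (cm^2) and weights (g); at least as many
#'   distinct points as coefficients, W positive where a log transform
#'   requires it.
#' @param area_coefficient carried into the returned spec.
#' @return A [comparator_spec()] with an `rss` attribute (residual sum of
#'   squares on the weight scale over the training pairs).
#' @export
fit_comparator <- function(form, A, W, area_coefficient = 1) {
  form <- match.arg(form, c("power_fixed", "power", "exponential",
                            "linear", "logarithmic", "polynomial2"))
  stopifnot(length(A) == length(W))
  arity <- if (form == "polynomial2") 3L else 2L
  if (length(unique(A)) < arity)
    stop("degenerate design: need at least ", arity, " distinct areas",
         call. = FALSE)
  if (form %in% c("power_fixed", "power", "exponential") && any(W <= 0)) {
    bad <- which(W <= 0)
    stop("nonpositive weights at rows ", paste(head(bad, 5), collapse = ", "),
         " cannot be log-transformed", call. = FALSE)
  }
  if (form %in% c("power_fixed", "power", "logarithmic") && any(A <= 0))
    stop("nonpositive areas cannot be log-transformed", call. = FALSE)
  ols <- function(x, y) {
    f <- lm.fit(cbind(1, x), y)
    unname(f$coefficients)
  }
  k <- switch(form,
    power_fixed = ,
    power = { b <- ols(log(A), log(W)); c(exp(b[1]), b[2]) },
    exponential = { b <- ols(A, log(W)); c(exp(b[1]), b[2]) },
    linear = { b <- ols(A, W); c(b[2], b[1]) },
    logarithmic = { b <- ols(log(A), W); c(b[2], b[1]) },
    polynomial2 = { b <- ols(cbind(A^2, A), W); c(b[2], b[3], b[1]) })
  spec <- comparator_spec(form, k, area_coefficient)
  attr(spec, "rss") <- sum((W - area_weight(spec, A))^2)
  spec
}

#' Head-to-head comparison of weight estimators
#'
#' Evaluates each area-based estimator and the cascade's predictions
#' against the same true weights, returning one metrics row per method.
#'
#' @param specs named list of [comparator_spec()]s (default all seven).
#' @param area body areas in cm^2, aligned with `actual_weights`.
#' @param cascade_pred cascade-predicted weights (g), same alignment; may
#'   be `NULL` to compare the area methods only.
#' @param actual_weights true weights (g).
#' @return data.frame with columns `label`, `mae`, `r2`, `mae_ratio`,
#'   `mean_error`, `sd_error`, `n`; one row per estimator plus a
#'   `cascade` row when predictions are given.
#' @export
compare_methods <- function(specs = default_comparators(), area,
                            cascade_pred = NULL, actual_weights) {
  if (!is.null(cascade_pred) && length(cascade_pred) != length(actual_weights))
    stop("cascade predictions misaligned with actual weights", call. = FALSE)
  if (length(area) != length(actual_weights))
    stop("areas misaligned with actual weights", call. = FALSE)
  rows <- lapply(names(specs), function(nm)
    as.data.frame(metrics_report(actual_weights,
                                 area_weight(specs[[nm]], area),
                                 label = nm)))
  if (!is.null(cascade_pred))
    rows <- c(rows, list(as.data.frame(
      metrics_report(actual_weights, cascade_pred, label = "cascade"))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.comparator_spec <- function(x, digits = 4, ...) {
  cat(sprintf("<comparator_spec> %s (%s): coefficients %s, area coefficient %g\n",
              x$label, x$form,
              paste(signif(x$coefficients, digits), collapse = ", "),
              x$area_coefficient))
  invisible(x)
}
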