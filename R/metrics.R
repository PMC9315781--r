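#' Evaluation metrics for weight, size, and depth estimates
#'
#' `mae()` is the mean absolute error; `r_squared()` the coefficient of
#' determination \eqn{1 - SS_{res}/SS_{tot}} (negative when predictions are
#' worse than the mean predictor, as happens out-of-sample); `mae_ratio()`
#' divides MAE by R-squared, a combined score in which lower is better and
#' a negative value flags a model worse than the mean predictor;
#' `error_stats()` returns the mean and sample standard deviation of the
#' signed errors (predicted minus actual).
#'
#' @param actual numeric vector of observed values.
#' @param predicted numeric vector of predictions, same length.
#' @return `mae()`, `r_squared()`, `mae_ratio()`: a single number.
#'   `error_stats()`: named numeric vector `c(mean_error, sd_error)`.
#' @examples
#' mae(c(10, 20), c(12, 26))        # 4
#' r_squared(c(1, 2, 3), c(1, 2, 2)) # 0.5
#' mae_ratio(42.54, 0.70)
#' @export
mae <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (length(actual) == 0L) stop("empty vectors", call. = FALSE)
  mean(abs(actual - predicted))
}

#' @rdname mae
#' @export
r_squared <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (length(actual) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("zero variance in 'actual'; R-squared undefined", call. = FALSE)
  1 - sum((actual - predicted)^2) / ss_tot
}

#' @rdname mae
#' @param mae_value a mean absolute error.
#' @param r2_value a coefficient of determination; must be nonzero.
#' @export
mae_ratio <- function(mae_value, r2_value) {
  stopifnot(is.numeric(mae_value), is.numeric(r2_value))
  if (any(r2_value == 0)) stop("MAE ratio undefined for R-squared of 0", call. = FALSE)
  mae_value / r2_value
}

#' @rdname mae
#' @export
error_stats <- function(actual, predicted) {
  check_paired(actual, predicted)
  if (length(actual) < 2L)
    stop("sample SD of errors needs at least 2 observations", call. = FALSE)
  err <- predicted - actual
  c(mean_error = mean(err), sd_error = sd(err))
}

check_paired <- function(actual, predicted) {
  if (!is.numeric(actual) || !is.numeric(predicted))
    stop("inputs must be numeric", call. = FALSE)
  if (length(actual) != length(predicted))
    stop(sprintf("length mismatch: %d vs %d", length(actual), length(predicted)),
         call. = FALSE)
  invisible(TRUE)
}

#' Summarise one prediction set as a metrics report
#'
#' Bundles MAE, R-squared, MAE ratio, and signed-error statistics for one
#' vector of predictions against its observed values — the row format used
#' throughout model evaluation tables.
#'
#' @inheritParams mae
#' @param label optional character tag identifying the model or stage.
#' @return An object of class `metrics_report`: a list with elements
#'   `label`, `mae`, `r2`, `mae_ratio`, `mean_error`, `sd_error`, `n`.
#' @export
metrics_report <- function(actual, predicted, label = NULL) {
  m <- mae(actual, predicted)
  r2 <- r_squared(actual, predicted)
  es <- error_stats(actual, predicted)
  structure(list(
    label = label, mae = m, r2 = r2,
    mae_ratio = if (r2 != 0) m / r2 else NA_real_,
    mean_error = unname(es["mean_error"]),
    sd_error = unname(es["sd_error"]),
    n = length(actual)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  if (!is.null(x$label)) cat(x$label, ": ", sep = "")
  cat(sprintf(
    "MAE %.*g | R2 %.*g | MAE ratio %.*g | mean err %.*g | SD err %.*g | n = %d\n",
    digits, x$mae, digits, x$r2, digits, x$mae_ratio,
    digits, x$mean_error, digits, x$sd_error, x$n))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(label = x$label %||% NA_character_, mae = x$mae, r2 = x$r2,
             mae_ratio = x$mae_ratio, mean_error = x$mean_error,
             sd_error = x$sd_error, n = x$n, stringsAsFactors = FALSE)
}
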