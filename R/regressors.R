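#' Regressor specification
#'
#' The cascade's stages can each use one of three regression families:
#' ordinary least-squares linear regression (`"lr"`), random forest
#' regression (`"rfr"`), or epsilon-insensitive support vector regression
#' with a radial basis function kernel (`"svr"`).
#'
#' Hyperparameters by family (unknown entries are rejected):
#' * `lr` — none; intercept and coefficients are solved exactly.
#' * `rfr` — `max_depth` (default 2, as used for the fish data),
#'   `n_estimators` (default 100), `min_samples_leaf` (default 5),
#'   `min_samples_split` (folded into the leaf control), `max_features`
#'   (default a third of the features).
#' * `svr` — `cost` (regularization parameter, default 10), `gamma`
#'   (kernel coefficient, default 0.1; the RBF kernel
#'   `exp(-||x1 - x2||^2 / (2 sigma^2))` has `gamma = 1/(2 sigma^2)`),
#'   `epsilon` (insensitive-tube width, default 0.1). Features are
#'   standardized to mean 0, SD 1 on the training set before fitting.
#'
#' @param family one of `"lr"`, `"rfr"`, `"svr"` (case-insensitive;
#'   `"LR"`, `"RFR"`, `"SVR"` also accepted).
#' @param ... named hyperparameters, see Details.
#' @return A list of class `regressor_spec`.
#' @export
regressor_spec <- function(family = c("lr", "rfr", "svr"), ...) {
  family <- tolower(family)
  family <- match.arg(family)
  hp <- list(...)
  allowed <- switch(family,
    lr = character(),
    rfr = c("max_depth", "n_estimators", "min_samples_leaf",
            "min_samples_split", "max_features"),
    svr = c("cost", "gamma", "epsilon"))
  bad <- setdiff(names(hp), allowed)
  if (length(bad))
    stop(sprintf("unknown %s hyperparameters: %s", toupper(family),
                 paste(bad, collapse = ", ")), call. = FALSE)
  num <- unlist(hp[names(hp) != ""])
  if (length(num) && any(num <= 0))
    stop("hyperparameters must be positive", call. = FALSE)
  structure(list(family = family, hyperparameters = hp),
            class = "regressor_spec")
}

#' RBF kernel value between two feature vectors
#'
#' `exp(-||x1 - x2||^2 / (2 sigma2))`, the radial basis function used by
#' the SVR family; equals 1 at zero distance.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param sigma2 positive variance hyperparameter.
#' @return A number in (0, 1].
#' @export
rbf_kernel <- function(x1, x2, sigma2 = 1) {
  stopifnot(length(x1) == length(x2), sigma2 > 0)
  exp(-sum((x1 - x2)^2) / (2 * sigma2))
}

#' Fit one regressor
#'
#' Dispatches on the spec's family: LR is solved exactly by QR least
#' squares with an intercept (falling back to the SVD minimum-norm
#' solution, with a warning, on rank-deficient designs); RFR is a
#' bootstrap ensemble of depth-limited regression trees minimizing
#' squared error; SVR is the epsilon-insensitive RBF machine fitted on
#' standardized features (predictions are returned on the original
#' scale).
#'
#' @param spec a [regressor_spec()].
#' @param features numeric matrix or data.frame (rows = samples).
#' @param targets numeric response vector.
#' @return An object of class `aqw_regressor` supporting `predict()` and
#'   `coef()` (LR only).
#' @examples
#' x <- matrix(1:10, ncol = 1)
#' f <- fit_regressor(regressor_spec("lr"), x, 1 + 2 * as.numeric(x))
#' coef(f)  # intercept 1, slope 2
#' @export
fit_regressor <- function(spec, features, targets) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(targets)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nrow(X) != length(y)) stop("features/targets length mismatch", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    lr = {
      Xi <- cbind(`(Intercept)` = 1, X)
      qr_fit <- lm.fit(Xi, y)
      if (qr_fit$rank < ncol(Xi)) {
        warning("rank-deficient design; using minimum-norm solution")
        sv <- svd(Xi)
        pos <- sv$d > max(sv$d) * 1e-10
        beta <- sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
        beta <- drop(beta)
        names(beta) <- colnames(Xi)
      } else beta <- qr_fit$coefficients
      list(coefficients = beta)
    },
    rfr = {
      depth <- hp$max_depth %||% 2
      randomForest::randomForest(
        x = X, y = y,
        ntree = hp$n_estimators %||% 100,
        maxnodes = 2^depth,
        nodesize = hp$min_samples_leaf %||% 5,
        mtry = hp$max_features %||% max(1, floor(ncol(X) / 3)))
    },
    svr = {
      scale_ok <- apply(X, 2, sd) > 0
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = hp$cost %||% 10, gamma = hp$gamma %||% 0.1,
                 epsilon = hp$epsilon %||% 0.1,
                 scale = scale_ok)
    })
  structure(list(spec = spec, fit = fit, p = ncol(X),
                 feature_names = colnames(X)),
            class = "aqw_regressor")
}

#' @export
predict.aqw_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$p)
    stop(sprintf("expected %d features, got %d", object$p, ncol(X)),
         call. = FALSE)
  switch(object$spec$family,
    lr = drop(cbind(1, X) %*% object$fit$coefficients),
    rfr = unname(predict(object$fit, X)),
    svr = {
      colnames(X) <- object$feature_names
      unname(predict(object$fit, X))
    })
}

#' @export
coef.aqw_regressor <- function(object, ...) {
  if (object$spec$family != "lr") return(NULL)
  object$fit$coefficients
}

#' @export
print.aqw_regressor <- function(x, ...) {
  hp <- x$spec$hyperparameters
  cat(sprintf("<aqw_regressor> %s, %d features%s\n", toupper(x$spec$family),
              x$p,
              if (length(hp)) paste0(" (", paste(names(hp), unlist(hp),
                                                 sep = "=", collapse = ", "),
                                     ")") else ""))
  invisible(x)
}

#' Exhaustive grid search over hyperparameters
#'
#' Fits every Cartesian combination of the supplied hyperparameter lists
#' on the training set and returns the spec with the smallest validation
#' MAE; ties go to the first combination in deterministic grid order
#' (the first list varying fastest).
#'
#' @param family regression family, as in [regressor_spec()].
#' @param grid named list of hyperparameter value vectors.
#' @param x_train,y_train training features and targets.
#' @param x_val,y_val validation features and targets (disjoint from
#'   training).
#' @param seed integer seed or `NULL` (the forest family is stochastic).
#' @return A list with `spec` (best [regressor_spec()]), `mae`
#'   (its validation MAE), and `results` (a data.frame of every
#'   combination and its MAE).
#' @export
grid_search <- function(family, grid, x_train, y_train, x_val, y_val,
                        seed = NULL) {
  if (is.null(grid) || length(grid) == 0L)
    stop("empty hyperparameter grid", call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(combos))
  with_seed(seed, {
    for (i in seq_len(nrow(combos))) {
      spec <- do.call(regressor_spec, c(list(family = family),
                                        as.list(combos[i, , drop = FALSE])))
      fit <- fit_regressor(spec, x_train, y_train)
      scores[i] <- mae(y_val, predict(fit, x_val))
    }
  })
  best <- which.min(scores)  # which.min takes the first minimum: tie rule
  best_spec <- do.call(regressor_spec,
                       c(list(family = family),
                         as.list(combos[best, , drop = FALSE])))
  list(spec = best_spec, mae = scores[best],
       results = cbind(combos, mae = scores))
}

#' Default hyperparameter grids per family
#'
#' The SVR grid spans regularization, kernel coefficient, and tube width;
#' the RFR grid keeps depth at 2 and varies leaf size and feature
#' subsampling; LR has nothing to tune (`NULL`).
#'
#' @param family regression family.
#' @return A named list of value vectors, or `NULL` for `"lr"`.
#' @export
default_grid <- function(family) {
  switch(tolower(family),
    svr = list(cost = c(0.1, 1, 10, 100),
               gamma = c(0.001, 0.01, 0.1, 1),
               epsilon = c(0.01, 0.1, 1)),
    rfr = list(max_depth = 2, n_estimators = c(50, 100),
               min_samples_leaf = c(1, 5), max_features = c(1, 2)),
    lr = NULL)
}
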