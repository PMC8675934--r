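#' Specify a regression model family
#'
#' A uniform specification over the three families the package compares:
#' ordinary least squares (`"linear"`), random forest (`"rf"`, via ranger)
#' and gradient-boosted trees (`"gbt"`, via xgboost). Hyperparameters not
#' relevant to a family are ignored by it.
#'
#' @param family one of `"linear"`, `"rf"`, `"gbt"`.
#' @param num_trees forest size (rf) (default 500).
#' @param mtry predictors sampled per split (rf); default one third of the
#'   predictor count.
#' @param min_node_size minimal terminal node size (rf).
#' @param max_depth maximal tree depth; `NULL` for unlimited (rf) / 6 (gbt).
#'   Capping depth is the main cost lever for large stacked frames.
#' @param nrounds boosting rounds (gbt) (default 500).
#' @param learning_rate boosting shrinkage (gbt).
#' @param seed integer seed; recorded so every fit is reproducible.
#' @return a `model_spec`.
#' @export
model_spec <- function(family = c("rf", "linear", "gbt"),
                       num_trees = 500, mtry = NULL, min_node_size = 5,
                       max_depth = NULL, nrounds = 500, learning_rate = 0.1,
                       seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth,
                 nrounds = nrounds, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "model_spec")
}

set_spec_seed <- function(spec, seed) { spec$seed <- as.integer(seed); spec }

#' Fit a regressor on a model frame
#'
#' Trains the specified family on the predictor columns of a stacked model
#' frame (abiotic features, competitor columns if present, and the one-hot
#' species identity block). The fitted model freezes the ordered feature
#' list; prediction refuses inputs with a different feature set.
#'
#' @param spec a [model_spec()].
#' @param frame a model frame from [build_model_frame()], carrying the
#'   target column.
#' @return a `trained_model`.
#' @export
fit_regressor <- function(spec, frame) {
  stopifnot(inherits(spec, "model_spec"))
  X <- frame_matrix(frame)
  y <- frame[[attr(frame, "target_col")]]
  if (nrow(X) == 0) stop_validation("cannot fit on an empty frame")
  if (ncol(X) == 0) stop_validation("frame has zero predictor columns")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_validation("non-finite values in predictors or target")
  }
  fit <- switch(spec$family,
    linear = {
      f <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      cf <- f$coefficients
      cf[is.na(cf)] <- 0  # aliased columns contribute nothing
      list(coefficients = cf)
    },
    rf = ranger::ranger(
      x = X, y = y,
      num.trees = spec$num_trees,
      mtry = spec$mtry %||% max(1L, floor(ncol(X) / 3)),
      min.node.size = spec$min_node_size,
      max.depth = spec$max_depth %||% 0,
      seed = spec$seed, num.threads = 1L,
      verbose = FALSE, oob.error = FALSE
    ),
    gbt = {
      xgboost::xgboost(
        x = X, y = y,
        objective = "reg:squarederror",
        nrounds = spec$nrounds,
        learning_rate = spec$learning_rate,
        max_depth = spec$max_depth %||% 6,
        nthreads = 1L, seed = spec$seed,
        verbosity = 0L
      )
    })
  structure(list(spec = spec, fit = fit, features = colnames(X),
                 target_range = range(y), n_train = nrow(X)),
            class = "trained_model")
}

#' Predict from a trained regressor
#'
#' Returns one real-valued prediction per row. Negative or fractional
#' predictions from the linear and boosted families are preserved as
#' predicted — never rounded or clipped — so model families can be compared
#' fairly; random forests cannot extrapolate outside the training target
#' range and therefore never predict negatives on non-negative targets.
#'
#' @param object a `trained_model`.
#' @param newdata a model frame or a numeric matrix whose columns match the
#'   training feature set.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else frame_matrix(newdata, intersect(c(frame_predictor_cols(newdata)), colnames(newdata)))
  missing <- setdiff(object$features, colnames(X))
  extra <- setdiff(colnames(X), object$features)
  if (length(missing) > 0 || length(extra) > 0) {
    stop_validation("feature set mismatch; missing: [%s], extra: [%s]",
                    paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  X <- X[, object$features, drop = FALSE]
  if (nrow(X) == 0) return(numeric(0))
  switch(object$spec$family,
    linear = as.numeric(cbind(1, X) %*% object$fit$coefficients),
    rf = as.numeric(stats::predict(object$fit, data = X, num.threads = 1L,
                                   verbose = FALSE)$predictions),
    gbt = as.numeric(stats::predict(object$fit, newdata = X))
  )
}
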