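#' Fit the two-step sequential stacked model
#'
#' Stage 1 fits a single cross-species model of abundance on abiotic
#' features plus species identity. Its predictions for every
#' (species, community) pair are then bound to the abiotic features as
#' predicted competitor-abundance columns — the focal species' own column
#' set to 0, as in the observed-competitor frame — and stage 2 is fitted on
#' that semi-synthetic frame. The resulting predictor needs only abiotic
#' data at deployment.
#'
#' @param table a [community_table()] of training communities.
#' @param stage1_spec [model_spec()] for the abiotic stage (default random
#'   forest).
#' @param stage2_spec [model_spec()] for the full stage.
#' @param stage1_features abiotic features for stage 1 (default: all).
#' @param stage2_features abiotic features for stage 2 (default: same as
#'   stage 1).
#' @param chaining `"in_sample"` (stage-1 predictions on its own training
#'   data feed stage-2 training) or `"out_of_fold"` (stage-1 predictions for
#'   each training community come from a model fitted without it;
#'   an anti-leakage variant).
#' @param n_folds folds for out-of-fold chaining (>= 2).
#' @param seed optional integer; when given, distinct sub-seeds are derived
#'   for the two stages so each is independently reproducible.
#' @return a `two_step_model`.
#' @export
fit_two_step <- function(table,
                         stage1_spec = model_spec("rf"),
                         stage2_spec = model_spec("rf"),
                         stage1_features = NULL,
                         stage2_features = NULL,
                         chaining = c("in_sample", "out_of_fold"),
                         n_folds = 5,
                         seed = NULL) {
  chaining <- match.arg(chaining)
  stage1_features <- stage1_features %||% abiotic_names(table)
  stage2_features <- stage2_features %||% stage1_features
  if (!is.null(seed)) {
    stage1_spec <- set_spec_seed(stage1_spec, derive_seed(seed, 101L))
    stage2_spec <- set_spec_seed(stage2_spec, derive_seed(seed, 202L))
  }
  sp <- species_names(table)
  n <- nrow(table)

  frame1 <- build_model_frame(table, stage1_features, include_competitors = FALSE)
  oob_rf <- chaining == "out_of_fold" && stage1_spec$family == "rf"
  stage1 <- if (oob_rf) {
    # a random forest carries its own out-of-fold estimate — out-of-bag
    # predictions — so the single fit serves both purposes
    X1 <- frame_matrix(frame1)
    fit <- ranger::ranger(
      x = X1, y = frame1$abundance,
      num.trees = stage1_spec$num_trees,
      mtry = stage1_spec$mtry %||% max(1L, floor(ncol(X1) / 3)),
      min.node.size = stage1_spec$min_node_size,
      max.depth = stage1_spec$max_depth %||% 0,
      seed = stage1_spec$seed, num.threads = 1L, verbose = FALSE,
      oob.error = TRUE)
    structure(list(spec = stage1_spec, fit = fit, features = colnames(X1),
                   target_range = range(frame1$abundance), n_train = nrow(X1)),
              class = "trained_model")
  } else {
    fit_regressor(stage1_spec, frame1)
  }

  pred1 <- if (chaining == "in_sample") {
    matrix(predict(stage1, frame1), n, length(sp))
  } else if (oob_rf) {
    p <- stage1$fit$predictions
    p[is.nan(p)] <- mean(frame1$abundance)  # rows never out-of-bag
    matrix(p, n, length(sp))
  } else {
    if (n_folds < 2) stop_validation("out-of-fold chaining requires at least 2 folds")
    folds <- with_seed(derive_seed(stage1_spec$seed, 7L),
                       sample(rep_len(seq_len(n_folds), n)))
    out <- matrix(NA_real_, n, length(sp))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      m_f <- fit_regressor(stage1_spec,
                           build_model_frame(subset_communities(table, tr),
                                             stage1_features, include_competitors = FALSE))
      frame_te <- build_model_frame(subset_communities(table, !tr),
                                    stage1_features, include_competitors = FALSE)
      out[!tr, ] <- matrix(predict(m_f, frame_te), sum(!tr), length(sp))
    }
    out
  }

  frame2 <- build_model_frame(table, stage2_features, include_competitors = TRUE)
  frame2 <- bind_competitor_predictions(frame2, pred1)
  stage2 <- fit_regressor(stage2_spec, frame2)

  structure(list(stage1 = stage1, stage2 = stage2,
                 stage1_features = stage1_features,
                 stage2_features = stage2_features,
                 species = sp, abiotic = abiotic_names(table),
                 chaining = chaining, seed = seed),
            class = "two_step_model")
}

# Records must carry only identifiers and abiotic data: the whole point of
# the two-step predictor is that no observed abundance enters at prediction
# time.
assert_abiotic_only <- function(model, records) {
  offending <- intersect(model$species, names(records))
  if (length(offending) > 0) {
    stop_validation(
      "prediction input must contain abiotic data only; observed abundance column(s) present: %s",
      paste(offending, collapse = ", "))
  }
  missing <- setdiff(union(model$stage1_features, model$stage2_features), names(records))
  if (length(missing) > 0) {
    stop_validation("abiotic records are missing feature(s): %s",
                    paste(missing, collapse = ", "))
  }
}

# Build the stacked abiotic prediction frame (no target) for a set of
# records, one row per (focal species, record).
prediction_frame <- function(records, features, species) {
  n <- nrow(records)
  m <- length(species)
  idx <- rep(seq_len(n), times = m)
  out <- tibble::as_tibble(records)[idx, intersect(c("plot", "subplot", "year"), names(records)), drop = FALSE]
  out$focal <- rep(species, each = n)
  for (f in features) out[[f]] <- records[[f]][idx]
  sp_cols <- paste0("sp_", species)
  for (i in seq_len(m)) {
    v <- numeric(n * m)
    if (n > 0) v[((i - 1L) * n + 1L):(i * n)] <- 1
    out[[sp_cols[i]]] <- v
  }
  structure(out, feature_cols = features, comp_cols = character(0),
            sp_cols = sp_cols, species = species, target_col = "abundance",
            class = c("model_frame", class(out)))
}

# Stage-1 predictions as a (records x species) matrix.
stage1_matrix <- function(model, records) {
  frame <- prediction_frame(records, model$stage1_features, model$species)
  matrix(predict(model$stage1, frame), nrow(records), length(model$species))
}

#' Predict abundances for all species from abiotic data only
#'
#' Invokes stage 1 once per species and record to fill the predicted
#' competitor columns, then returns the stage-2 prediction for every
#' (record, species) pair. Inputs containing observed abundance columns are
#' rejected to enforce the interface contract.
#'
#' @param model a `two_step_model`.
#' @param records data frame of identifiers plus abiotic features.
#' @return tidy long tibble: identifier columns, `species`, `prediction`.
#' @export
predict_two_step <- function(model, records) {
  assert_abiotic_only(model, records)
  P1 <- stage1_matrix(model, records)
  frame2 <- prediction_frame(records, model$stage2_features, model$species)
  n <- nrow(records); m <- length(model$species)
  idx <- rep(seq_len(n), times = m)
  comp <- P1[idx, , drop = FALSE]
  for (i in seq_len(m)) comp[((i - 1L) * n + 1L):(i * n), i] <- 0
  comp_cols <- paste0("comp_", model$species)
  for (j in seq_len(m)) frame2[[comp_cols[j]]] <- comp[, j]
  attr(frame2, "comp_cols") <- comp_cols
  pred <- predict(model$stage2, frame2)
  long_predictions(records, model$species, pred)
}

#' Stage-1 (abiotic-only) predictions
#'
#' The first-stage model on its own: per-species abundance predicted from
#' abiotic features and species identity, ignoring species interactions.
#' These are exactly the values bound as predicted competitor columns by
#' [predict_two_step()].
#'
#' @inheritParams predict_two_step
#' @return tidy long tibble: identifier columns, `species`, `prediction`.
#' @export
predict_stage1 <- function(model, records) {
  assert_abiotic_only(model, records)
  P1 <- stage1_matrix(model, records)
  long_predictions(records, model$species, as.vector(P1))
}

long_predictions <- function(records, species, pred) {
  n <- nrow(records)
  id_cols <- intersect(c("plot", "subplot", "year"), names(records))
  out <- tibble::as_tibble(records)[rep(seq_len(n), times = length(species)), id_cols, drop = FALSE]
  out$species <- rep(species, each = n)
  out$prediction <- as.numeric(pred)
  tibble::as_tibble(out)
}
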