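#' Root mean square error
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return sqrt of the mean squared difference; symmetric in its arguments.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_validation("length mismatch: %d vs %d", length(y), length(yhat))
  if (length(y) == 0) stop_validation("empty vectors")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' Standard form: 1 - sum((y - yhat)^2) / sum((y - mean(y))^2). May be
#' negative when the predictor is worse than the mean of the observations.
#'
#' @inheritParams rmse
#' @return R squared.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_validation("length mismatch: %d vs %d", length(y), length(yhat))
  if (length(y) < 2) stop_validation("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop_validation("zero-variance target: R squared undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Relative squared error
#'
#' `RSE = 1 - R^2`; convenient for log-scale per-species error plots.
#'
#' @inheritParams rmse
#' @export
rse <- function(y, yhat) 1 - r_squared(y, yhat)

#' Spatial block K-fold assignment
#'
#' Groups subplots into contiguous axis-aligned spatial blocks within each
#' plot and deals whole blocks to `k` folds, balancing subplot counts. All
#' years of a subplot share its fold, so held-out locations are never seen
#' at training time in any year.
#'
#' @param sites a [community_table()] or data frame with `plot`, `subplot`,
#'   `x`, `y` (one row per subplot suffices; duplicates are collapsed).
#' @param k number of folds (>= 2).
#' @param block block window size in metres, `c(width, height)`.
#' @param seed integer seed for dealing blocks.
#' @return a `fold_assignment` tibble: `plot`, `subplot`, `fold`.
#' @export
spatial_block_kfold <- function(sites, k = 4, block = c(3, 3), seed = 1) {
  if (k < 2) stop_validation("k must be at least 2")
  df <- tibble::as_tibble(sites)[c("plot", "subplot", "x", "y")]
  df <- df[!duplicated(paste(df$plot, df$subplot, sep = "\r")), , drop = FALSE]
  x0 <- stats::ave(df$x, df$plot, FUN = min)
  y0 <- stats::ave(df$y, df$plot, FUN = min)
  block_id <- paste(df$plot,
                    (df$x - x0) %/% block[1],
                    (df$y - y0) %/% block[2], sep = ":")
  blocks <- unique(block_id)
  if (length(blocks) < k) {
    stop_validation("only %d spatial blocks for %d folds; use smaller blocks or fewer folds",
                    length(blocks), k)
  }
  sizes <- table(block_id)[blocks]
  ord <- with_seed(derive_seed(seed, 31L), sample.int(length(blocks)))
  fold_of_block <- integer(length(blocks))
  fold_size <- numeric(k)
  for (b in ord) {  # largest-remaining greedy balance
    f <- which.min(fold_size)
    fold_of_block[b] <- f
    fold_size[f] <- fold_size[f] + sizes[b]
  }
  out <- tibble::tibble(plot = df$plot, subplot = df$subplot,
                        fold = fold_of_block[match(block_id, blocks)])
  structure(out, scheme = "spatial-block", k = k, block = block,
            class = c("fold_assignment", class(out)))
}

#' Per-species prediction metrics
#'
#' RMSE, R squared and RSE computed separately for each species' slice of a
#' stacked prediction vector. Species whose observed values have zero
#' variance in the slice are flagged and not scored for R squared.
#'
#' @param observed observed abundances.
#' @param predicted predictions, aligned with `observed`.
#' @param species species label per element.
#' @param species_levels optional allowed label set; labels outside it raise
#'   an error.
#' @return tibble: `species`, `n`, `rmse`, `r2`, `rse`, `flagged`.
#' @export
per_species_metrics <- function(observed, predicted, species,
                                species_levels = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) == length(species))
  if (!is.null(species_levels)) {
    bad <- setdiff(unique(species), species_levels)
    if (length(bad) > 0) stop_validation("unknown species label(s): %s", paste(bad, collapse = ", "))
  }
  levs <- species_levels %||% unique(species)
  rows <- lapply(levs, function(s) {
    sel <- species == s
    n <- sum(sel)
    if (n == 0 || stats::var(observed[sel]) == 0 || n < 2) {
      tibble::tibble(species = s, n = n,
                     rmse = if (n > 0) rmse(observed[sel], predicted[sel]) else NA_real_,
                     r2 = NA_real_, rse = NA_real_, flagged = TRUE)
    } else {
      r2 <- r_squared(observed[sel], predicted[sel])
      tibble::tibble(species = s, n = n, rmse = rmse(observed[sel], predicted[sel]),
                     r2 = r2, rse = 1 - r2, flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Moran's I spatial autocorrelation
#'
#' Standard global Moran's I with a choice of neighbour weighting:
#' inverse-distance weights among all site pairs, or rook adjacency on a
#' unit grid. Weights are row-standardized by default.
#'
#' @param values numeric vector, one value per site.
#' @param coords two-column matrix or data frame of site coordinates.
#' @param scheme `"inverse_distance"` or `"rook"`.
#' @param row_standardize divide each weight row by its sum.
#' @return Moran's I.
#' @export
morans_i <- function(values, coords, scheme = c("inverse_distance", "rook"),
                     row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- length(values)
  if (n < 3) stop_validation("Moran's I needs at least 3 sites")
  if (stats::var(values) == 0) stop_validation("zero-variance values: Moran's I undefined")
  W <- morans_weights(as.matrix(coords), scheme, row_standardize)
  z <- values - mean(values)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

morans_weights <- function(xy, scheme, row_standardize) {
  d <- as.matrix(stats::dist(xy))
  W <- if (scheme == "inverse_distance") {
    w <- 1 / d; diag(w) <- 0; w[!is.finite(w)] <- 0; w
  } else {
    (abs(outer(xy[, 1], xy[, 1], "-")) + abs(outer(xy[, 2], xy[, 2], "-")) == 1) * 1
  }
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  W
}

#' Per-species Moran's I across plot-year fields
#'
#' For each species, computes Moran's I of subplot abundances separately in
#' every (plot, year) field — row-standardized inverse-distance weights
#' among subplot centroids — and averages over fields. Fields where the
#' species' abundance is constant carry no autocorrelation signal and are
#' skipped.
#'
#' @param table a [community_table()] with `x`, `y` columns.
#' @param scheme weighting scheme, see [morans_i()].
#' @return tibble: `species`, `morans_i` (mean over fields), `n_fields`.
#' @export
species_morans_i <- function(table, scheme = "inverse_distance") {
  sp <- species_names(table)
  key <- paste(table$plot, table$year, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  # subplot coordinates are constant across years: one weight matrix per plot
  Wcache <- new.env(parent = emptyenv())
  rows <- lapply(sp, function(s) {
    vals <- table[[s]]
    is <- numeric(0)
    for (g in groups) {
      v <- vals[g]
      if (length(g) < 3 || stats::var(v) == 0) next
      pl <- table$plot[g[1]]
      W <- get0(pl, envir = Wcache)
      if (is.null(W)) {
        W <- morans_weights(cbind(table$x[g], table$y[g]), scheme, TRUE)
        assign(pl, W, envir = Wcache)
      }
      z <- v - mean(v)
      is <- c(is, (length(v) / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2))
    }
    tibble::tibble(species = s,
                   morans_i = if (length(is) > 0) mean(is) else NA_real_,
                   n_fields = length(is))
  })
  do.call(rbind, rows)
}

#' Specify an evaluation pipeline
#'
#' Names which predictor is being evaluated — the all-features model
#' (abiotic + observed competitor abundances), the abiotic-only model, or
#' the two-step stacked model — together with its model specs and feature
#' sets.
#'
#' @param model `"all_features"`, `"abiotic"` or `"two_step"`.
#' @param spec [model_spec()] for the predictor (stage 2 when two-step).
#' @param stage1_spec [model_spec()] for the two-step first stage; defaults
#'   to `spec`.
#' @param features abiotic feature set (default: all abiotic columns).
#' @param chaining chaining mode for the two-step model.
#' @param per_species also record per-species metrics on every run.
#' @return a `pipeline_spec`.
#' @export
pipeline_spec <- function(model = c("two_step", "all_features", "abiotic"),
                          spec = model_spec("rf"), stage1_spec = NULL,
                          features = NULL,
                          chaining = c("in_sample", "out_of_fold"),
                          per_species = FALSE) {
  model <- match.arg(model)
  structure(list(model = model, spec = spec,
                 stage1_spec = stage1_spec %||% spec,
                 features = features, chaining = match.arg(chaining),
                 per_species = per_species),
            class = "pipeline_spec")
}

# Fit the pipeline on the training communities and score it on the test
# communities. Returns aligned observed/predicted vectors with labels.
fit_score <- function(table, pipeline, train, seed = 1,
                      drop_features = NULL) {
  stopifnot(is.logical(train), length(train) == nrow(table))
  features <- setdiff(pipeline$features %||% abiotic_names(table), drop_features)
  sp <- species_names(table)
  test <- !train
  if (!any(test)) stop_validation("test split is empty")
  if (!any(train)) stop_validation("training split is empty")

  if (pipeline$model == "two_step") {
    fit <- fit_two_step(subset_communities(table, train),
                        stage1_spec = pipeline$stage1_spec,
                        stage2_spec = pipeline$spec,
                        stage1_features = features,
                        chaining = pipeline$chaining,
                        seed = seed)
    rec <- tibble::as_tibble(unclass_table(table))[test, setdiff(names(table), sp), drop = FALSE]
    pred_long <- predict_two_step(fit, rec)
    obs <- unlist(lapply(sp, function(s) table[[s]][test]), use.names = FALSE)
    list(observed = as.numeric(obs), predicted = pred_long$prediction,
         species = pred_long$species,
         year = rep(table$year[test], times = length(sp)))
  } else {
    frame <- build_model_frame(table, features,
                               include_competitors = pipeline$model == "all_features")
    rows_train <- rep(train, times = length(sp))
    spec <- set_spec_seed(pipeline$spec, derive_seed(seed, 77L))
    fit <- fit_regressor(spec, subset_frame(frame, rows_train))
    fte <- subset_frame(frame, !rows_train)
    list(observed = fte$abundance, predicted = predict(fit, fte),
         species = fte$focal, year = fte$year)
  }
}

score_records <- function(scored, pipeline, id) {
  g <- tibble::tibble(scope = "global", species = NA_character_,
                      n = length(scored$observed),
                      rmse = rmse(scored$observed, scored$predicted),
                      r2 = r_squared(scored$observed, scored$predicted))
  g$rse <- 1 - g$r2
  out <- cbind(id, g)
  if (isTRUE(pipeline$per_species)) {
    ps <- per_species_metrics(scored$observed, scored$predicted, scored$species)
    ps <- tibble::tibble(scope = "species", species = ps$species, n = ps$n,
                         rmse = ps$rmse, r2 = ps$r2, rse = ps$rse)
    out <- rbind(out, cbind(id, ps))
  }
  tibble::as_tibble(out)
}

run_distribution <- function(records) {
  g <- records[records$scope == "global", , drop = FALSE]
  structure(list(records = tibble::as_tibble(records),
                 medians = list(r2 = stats::median(g$r2),
                                rmse = stats::median(g$rmse))),
            class = "run_distribution")
}

#' @export
print.run_distribution <- function(x, ...) {
  g <- x$records[x$records$scope == "global", ]
  cat(sprintf("Run distribution over %d evaluations\n", nrow(g)))
  cat(sprintf("  median R2   : %.3f\n", x$medians$r2))
  cat(sprintf("  median RMSE : %.3f\n", x$medians$rmse))
  invisible(x)
}

#' Repeated random 80/20 split evaluation
#'
#' For each run, holds out a random fraction of communities (all species
#' rows of a community move together), fits the pipeline on the rest and
#' scores the held-out predictions globally (and optionally per species).
#'
#' @param table a [community_table()].
#' @param pipeline a [pipeline_spec()].
#' @param n_runs number of random splits (the reference protocol uses 100).
#' @param test_fraction held-out fraction of communities (default 0.2).
#' @param seed integer seed; run r uses a sub-seed derived from it.
#' @return a `run_distribution`.
#' @export
repeated_random_split_eval <- function(table, pipeline, n_runs = 100,
                                       test_fraction = 0.2, seed = 1) {
  if (n_runs < 1) stop_validation("n_runs must be positive")
  if (test_fraction <= 0 || test_fraction >= 1) stop_validation("test_fraction must be in (0,1)")
  n <- nrow(table)
  n_test <- max(1L, round(test_fraction * n))
  if (n_test >= n) stop_validation("test split leaves no training data")
  records <- lapply(seq_len(n_runs), function(r) {
    rs <- derive_seed(seed, 1000L + r)
    test_ix <- with_seed(rs, sample.int(n, n_test))
    train <- rep(TRUE, n); train[test_ix] <- FALSE
    scored <- fit_score(table, pipeline, train, seed = rs)
    score_records(scored, pipeline,
                  tibble::tibble(run = r, fold = NA_integer_, year = NA_integer_))
  })
  run_distribution(do.call(rbind, records))
}

#' Spatial block cross-validation evaluation
#'
#' Assigns subplots to spatial blocks ([spatial_block_kfold()]), then holds
#' out each fold in turn: the pipeline is fitted on the remaining
#' communities of all years and scored at the held-out locations.
#'
#' @inheritParams repeated_random_split_eval
#' @param k number of spatial folds.
#' @param block spatial block size in metres.
#' @param folds subset of folds to evaluate (default: all); evaluating a
#'   single fold per seed is a cheap unbiased protocol for comparing
#'   pipelines across many seeds.
#' @return a `run_distribution` with one global record per fold.
#' @export
spatial_cv_eval <- function(table, pipeline, k = 4, block = c(3, 3),
                            seed = 1, folds = NULL) {
  assign <- spatial_block_kfold(table, k = k, block = block, seed = seed)
  key <- paste(table$plot, table$subplot, sep = "\r")
  fold_of_row <- assign$fold[match(key, paste(assign$plot, assign$subplot, sep = "\r"))]
  folds <- folds %||% seq_len(k)
  records <- lapply(folds, function(f) {
    scored <- fit_score(table, pipeline, fold_of_row != f,
                        seed = derive_seed(seed, 500L + f))
    score_records(scored, pipeline,
                  tibble::tibble(run = NA_integer_, fold = f, year = NA_integer_))
  })
  run_distribution(do.call(rbind, records))
}

#' Leave-one-year-out temporal evaluation
#'
#' Holds out each year in turn; training uses all remaining years,
#' including years after the held-out one — the protocol evaluates the
#' procedure, it is not a forecast. Optionally removes the precipitation
#' feature, the only year-level predictor.
#'
#' @inheritParams repeated_random_split_eval
#' @param drop_precipitation remove `precipitation` from the feature set.
#' @return a `run_distribution` with one global record per held-out year.
#' @export
leave_one_year_out_eval <- function(table, pipeline,
                                    drop_precipitation = FALSE, seed = 1) {
  years <- sort(unique(table$year))
  if (length(years) < 2) stop_validation("temporal evaluation needs at least 2 distinct years")
  records <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    scored <- fit_score(table, pipeline, table$year != yr,
                        seed = derive_seed(seed, 900L + i),
                        drop_features = if (drop_precipitation) "precipitation")
    score_records(scored, pipeline,
                  tibble::tibble(run = NA_integer_, fold = NA_integer_, year = yr))
  })
  run_distribution(do.call(rbind, records))
}
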