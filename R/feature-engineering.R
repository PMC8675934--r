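#' Spearman correlation-cluster filter
#'
#' Groups abiotic features into clusters by transitive closure of
#' `|rho| >= threshold` on pairwise Spearman correlations and keeps a single
#' representative per cluster; singleton features are always kept. Constant
#' features (undefined correlation) are flagged, excluded from clustering
#' and kept.
#'
#' @param table a [community_table()].
#' @param threshold absolute Spearman correlation above which two features
#'   are considered redundant (default 0.7).
#' @param keep_policy `"manual"` keeps the member listed first in `keep`;
#'   `"importance"` keeps the member with the highest impurity importance in
#'   a small preliminary random-forest fit; `"first"` keeps the member that
#'   appears first in the candidate list.
#' @param keep preferred representatives for `"manual"` policy (a cluster
#'   containing one of these keeps it).
#' @param candidates candidate feature names (default: all abiotic columns).
#' @param seed seed for the preliminary importance fit.
#' @return a `selection_report` list: `rho`, `clusters`, `kept`, `dropped`,
#'   `constant`, and a `provenance` tibble with a reason per feature.
#' @export
spearman_cluster_filter <- function(table, threshold = 0.7,
                                    keep_policy = c("importance", "manual", "first"),
                                    keep = NULL, candidates = NULL, seed = 1) {
  keep_policy <- match.arg(keep_policy)
  if (threshold <= 0 || threshold >= 1) stop_validation("threshold must be in (0,1)")
  candidates <- candidates %||% abiotic_names(table)
  if (length(candidates) < 2) stop_validation("need at least 2 candidate features")
  X <- as.matrix(tibble::as_tibble(unclass_table(table))[candidates])
  constant <- candidates[apply(X, 2, function(v) stats::sd(v) == 0)]
  active <- setdiff(candidates, constant)
  rho <- stats::cor(X[, active, drop = FALSE], method = "spearman")

  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  comp <- integer(length(active)); names(comp) <- active
  cid <- 0L
  for (v in active) {
    if (comp[v] > 0) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cid
      queue <- c(queue, active[adj[u, ] & comp[active] == 0])
    }
  }
  clusters <- split(names(comp), comp)
  clusters <- clusters[vapply(clusters, length, 1L) > 1]

  prelim_imp <- NULL
  if (keep_policy == "importance" && length(clusters) > 0) {
    prelim_imp <- prelim_importance(table, candidates = active, seed = seed)
  }
  kept <- active
  reasons <- stats::setNames(rep("singleton", length(active)), active)
  for (cl in clusters) {
    rep_ <- switch(keep_policy,
      manual = {
        pref <- intersect(keep %||% character(0), cl)
        if (length(pref) > 0) pref[1] else cl[1]
      },
      importance = cl[which.max(prelim_imp[cl])],
      first = cl[1])
    drop <- setdiff(cl, rep_)
    kept <- setdiff(kept, drop)
    reasons[drop] <- "correlation-cluster"
    reasons[rep_] <- "cluster-representative"
  }
  kept <- c(kept, constant)
  reasons[constant] <- "constant-kept"

  structure(list(
    rho = rho, threshold = threshold, clusters = unname(clusters),
    kept = intersect(candidates, kept),
    dropped = setdiff(candidates, kept),
    constant = constant,
    importance = NULL,
    provenance = tibble::tibble(feature = candidates,
                                kept = candidates %in% kept,
                                reason = unname(reasons[candidates]))
  ), class = "selection_report")
}

# Impurity importance from a quick forest on a subsample of the stacked
# abiotic frame; used only to pick cluster representatives.
prelim_importance <- function(table, candidates, seed = 1) {
  frame <- build_model_frame(table, candidates, include_competitors = FALSE)
  n <- nrow(frame)
  ix <- if (n > 5000) with_seed(derive_seed(seed, 3L), sample.int(n, 5000)) else seq_len(n)
  fit <- ranger::ranger(x = frame_matrix(subset_frame(frame, ix)),
                        y = frame$abundance[ix],
                        num.trees = 100, importance = "impurity",
                        seed = derive_seed(seed, 4L), num.threads = 1L,
                        verbose = FALSE)
  imp <- fit$variable.importance
  imp[candidates]
}

#' Permutation importance with a random-noise benchmark
#'
#' Appends a uniform random-noise column to the frame, fits the model on an
#' 80% split, and measures each feature's permutation importance on the
#' held-out 20%: the mean drop in R squared over `n_repeats` shuffles of
#' that feature. The species-identity one-hot block is permuted jointly as
#' a single `species` feature. The noise feature provides an empirical
#' floor: features whose importance is indistinguishable from noise carry
#' no usable signal.
#'
#' @param frame a model frame from [build_model_frame()].
#' @param spec a [model_spec()].
#' @param seed integer seed (noise column, split and shuffles).
#' @param n_repeats shuffle repetitions per feature (default 10).
#' @param eval_fraction held-out fraction used for scoring (default 0.2).
#' @return tibble `feature`, `importance`, `se`, sorted by decreasing
#'   importance, with exactly one `random_noise` row; baseline R squared in
#'   attribute `baseline_r2`.
#' @export
noise_benchmark_importance <- function(frame, spec, seed = 1, n_repeats = 10,
                                       eval_fraction = 0.2) {
  n <- nrow(frame)
  if (n < 10) stop_validation("insufficient data for permutation importance (%d rows)", n)
  frame$random_noise <- with_seed(derive_seed(seed, 41L), stats::runif(n))
  attr(frame, "feature_cols") <- c(attr(frame, "feature_cols"), "random_noise")

  n_eval <- max(2L, round(eval_fraction * n))
  eval_ix <- with_seed(derive_seed(seed, 42L), sample.int(n, n_eval))
  train <- subset_frame(frame, setdiff(seq_len(n), eval_ix))
  hold <- subset_frame(frame, eval_ix)
  fit <- fit_regressor(set_spec_seed(spec, derive_seed(seed, 43L)), train)
  Xh <- frame_matrix(hold)
  y <- hold$abundance
  base_r2 <- r_squared(y, predict(fit, Xh))

  groups <- c(as.list(stats::setNames(nm = c(attr(frame, "feature_cols"),
                                             attr(frame, "comp_cols")))),
              if (length(attr(frame, "sp_cols")) > 0) list(species = attr(frame, "sp_cols")))
  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- Xh
      perm <- with_seed(derive_seed(seed, 5000L + r * 131L + nchar(g) + sum(utf8ToInt(g))),
                        sample.int(nrow(Xh)))
      Xp[, cols] <- Xh[perm, cols, drop = FALSE]
      base_r2 - r_squared(y, predict(fit, Xp))
    }, numeric(1))
    tibble::tibble(feature = g, importance = mean(drops),
                   se = stats::sd(drops) / sqrt(n_repeats))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance), , drop = FALSE]
  attr(out, "baseline_r2") <- base_r2
  out
}

#' Final feature selection from a report
#'
#' Applies the below-noise rule and manual overrides to the features kept by
#' the correlation filter. A feature is "below noise" when its permutation
#' importance does not exceed the noise feature's importance by more than
#' two standard errors of the noise estimate — a pure-noise feature and a
#' feature with no true effect are statistically exchangeable, so the band
#' keeps the rule honest.
#'
#' @param report a `selection_report` from [spearman_cluster_filter()], with
#'   an `importance` element (attach the output of
#'   [noise_benchmark_importance()]).
#' @param drop_below_noise drop features below the noise benchmark.
#' @param override_keep features retained regardless of the rules.
#' @param override_drop features dropped regardless of the rules.
#' @return list with `retained` (character vector) and `provenance` tibble.
#' @export
select_features <- function(report, drop_below_noise = TRUE,
                            override_keep = NULL, override_drop = NULL) {
  candidates <- report$kept
  bad <- setdiff(c(override_keep, override_drop), c(candidates, report$dropped))
  if (length(bad) > 0) stop_validation("override names unknown feature(s): %s",
                                       paste(bad, collapse = ", "))
  reasons <- stats::setNames(rep("kept", length(candidates)), candidates)
  retained <- candidates
  imp <- report$importance
  if (drop_below_noise) {
    if (is.null(imp)) stop_validation("report carries no importance table; run noise_benchmark_importance first")
    noise <- imp[imp$feature == "random_noise", , drop = FALSE]
    if (nrow(noise) != 1) stop_validation("importance table must contain exactly one noise entry")
    bar <- noise$importance + 2 * noise$se
    scored <- imp$feature[imp$feature %in% candidates]
    below <- scored[imp$importance[match(scored, imp$feature)] <= bar]
    retained <- setdiff(retained, below)
    reasons[below] <- "below-noise"
  }
  if (length(override_drop) > 0) {
    retained <- setdiff(retained, override_drop)
    reasons[intersect(override_drop, candidates)] <- "manual-override-drop"
  }
  if (length(override_keep) > 0) {
    add <- intersect(override_keep, candidates)
    retained <- union(retained, add)
    reasons[add] <- "manual-override-keep"
  }
  list(retained = intersect(candidates, retained),
       provenance = tibble::tibble(feature = candidates,
                                   retained = candidates %in% retained,
                                   reason = unname(reasons[candidates])))
}

#' Curated feature selection for the 13-variable soil panel
#'
#' The selection shipped with the package for the Mediterranean
#' salinity-gradient survey design: the correlation filter collapses the
#' fertility cluster \{C, organic_matter, N, cn_ratio\} onto `C` and the
#' salinity cluster \{salinity, Na, Cl, K\} onto `salinity`; the noise
#' benchmark then drops `pH` and `Mg`, while `Ca` is retained by explicit
#' override despite ranking near the noise floor. The abiotic model keeps 6
#' features; the full (all-features and two-step) models additionally keep
#' `Mg` and `pH`, whose importance rank is higher for gradient boosting.
#'
#' @return a list with the drop lists, overrides and the two retained sets.
#' @export
curated_selection <- function() {
  list(
    correlation_drop = c("organic_matter", "N", "cn_ratio", "Na", "Cl", "K"),
    correlation_keep = c("C", "salinity"),
    below_noise_drop = c("pH", "Mg"),
    override_keep = "Ca",
    abiotic_model = c("salinity", "precipitation", "C", "Ca", "P", "carbonates"),
    full_model = c("salinity", "precipitation", "C", "Ca", "P", "carbonates",
                   "Mg", "pH")
  )
}

#' Apply the curated selection to a candidate feature list
#'
#' @param candidates candidate abiotic features (default:
#'   [default_schema()]'s abiotic set).
#' @param model `"abiotic"` (drops the below-noise features) or `"full"`
#'   (keeps `Mg` and `pH`).
#' @return the retained feature character vector.
#' @export
apply_curated_selection <- function(candidates = default_schema()$abiotic,
                                    model = c("abiotic", "full")) {
  model <- match.arg(model)
  cur <- curated_selection()
  retained <- setdiff(candidates, cur$correlation_drop)
  if (model == "abiotic") retained <- setdiff(retained, cur$below_noise_drop)
  retained <- union(retained, intersect(cur$override_keep, candidates))
  intersect(candidates, retained)
}
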