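test_that("the correlation filter collapses the soil clusters onto the chosen representatives", {
  tab <- simulate_community(seed = 1)$table
  rep <- spearman_cluster_filter(tab, threshold = 0.7, keep_policy = "manual",
                                 keep = c("C", "salinity"))
  expect_setequal(rep$dropped,
                  c("organic_matter", "N", "cn_ratio", "Na", "Cl", "K"))
  expect_true(all(c("C", "salinity", "carbonates", "P", "Ca", "pH", "Mg",
                    "precipitation") %in% rep$kept))
  expect_equal(length(rep$clusters), 2)
  expect_setequal(rep$provenance$feature, abiotic_names(tab))
  expect_true(all(rep$provenance$reason[rep$provenance$feature %in% rep$dropped] ==
                    "correlation-cluster"))
})

test_that("duplicated, uncorrelated and constant features are handled", {
  set.seed(31)
  n <- 200
  df <- tibble::tibble(plot = "P1", subplot = sprintf("S%03d", 1:n),
                       year = 2015L, x = 1:n, y = 0,
                       f1 = rnorm(n), f3 = rnorm(n), f4 = 7,
                       SPA = rpois(n, 2))
  df$f2 <- df$f1  # identical copy, rho = 1
  tab <- community_table(df, species = "SPA",
                         abiotic = c("f1", "f2", "f3", "f4"))
  rep <- spearman_cluster_filter(tab, threshold = 0.99, keep_policy = "first")
  expect_equal(length(rep$dropped), 1)
  expect_true(rep$dropped %in% c("f1", "f2"))
  # constant feature flagged and kept, excluded from clustering
  expect_equal(rep$constant, "f4")
  expect_true("f4" %in% rep$kept)

  # nothing correlated above threshold: identity
  rep2 <- spearman_cluster_filter(tab, threshold = 0.99,
                                  candidates = c("f1", "f3"))
  expect_equal(rep2$dropped, character(0))
})

test_that("under a feature-independent target nothing beats the noise benchmark", {
  tab <- tiny_table(seed = 2)
  frame <- build_model_frame(tab, include_competitors = FALSE)
  set.seed(8)
  frame$abundance <- rnorm(nrow(frame))  # target carries no signal
  imp <- noise_benchmark_importance(frame, rf_spec(num_trees = 50), seed = 3,
                                    n_repeats = 8)
  noise <- imp[imp$feature == "random_noise", ]
  expect_equal(nrow(noise), 1)
  # every candidate is exchangeable with the injected noise: the model has
  # no skill and no feature shows a materially positive performance drop
  expect_lt(abs(attr(imp, "baseline_r2")), 0.3)
  expect_lt(max(abs(imp$importance)), 0.15)
})

test_that("a strong engineered predictor ranks first, above noise", {
  tab <- tiny_table(seed = 4)
  frame <- build_model_frame(tab, include_competitors = FALSE)
  set.seed(9)
  frame$abundance <- 3 * frame$P + rnorm(nrow(frame), 0, 0.2)
  imp <- noise_benchmark_importance(frame, rf_spec(), seed = 5)
  expect_equal(imp$feature[1], "P")
  noise_imp <- imp$importance[imp$feature == "random_noise"]
  expect_gt(imp$importance[1], noise_imp + 10 * imp$se[imp$feature == "random_noise"])
})

test_that("permutation importance refuses frames too small to split", {
  tab <- tiny_table()
  frame <- build_model_frame(tab, include_competitors = FALSE)
  expect_error(noise_benchmark_importance(commstack:::subset_frame(frame, 1:4),
                                          rf_spec(), seed = 1),
               "insufficient data")
})

test_that("on the default community the importance ranking mirrors the field pattern", {
  tab <- simulate_community(seed = 1)$table
  kept <- apply_curated_selection(model = "full")
  frame <- build_model_frame(tab, features = kept, include_competitors = FALSE)
  imp <- noise_benchmark_importance(frame, rf_spec(num_trees = 80, seed = 2),
                                    seed = 2, n_repeats = 6)
  abiotic_rank <- imp$feature[imp$feature %in% kept]
  # precipitation dominates among abiotic features
  expect_equal(abiotic_rank[1], "precipitation")
  bar <- imp$importance[imp$feature == "random_noise"] +
    2 * imp$se[imp$feature == "random_noise"]
  # the two variables with no true effect fall below the noise benchmark,
  # the real drivers clear it
  for (f in c("pH", "Mg")) {
    expect_lte(imp$importance[imp$feature == f], bar)
  }
  for (f in c("carbonates", "C", "P")) {
    expect_gt(imp$importance[imp$feature == f], bar)
  }
})

test_that("a feature with a true zero effect falls below noise in at least 90% of seeds", {
  hits <- vapply(1:20, function(s) {
    tab <- simulate_community(seed = 100 + s)$table
    frame <- build_model_frame(tab, features = apply_curated_selection(model = "full"),
                               include_competitors = FALSE)
    imp <- noise_benchmark_importance(frame,
                                      rf_spec(num_trees = 50, max_depth = 12, seed = s),
                                      seed = s, n_repeats = 4)
    bar <- imp$importance[imp$feature == "random_noise"] +
      2 * imp$se[imp$feature == "random_noise"]
    imp$importance[imp$feature == "pH"] <= bar
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("selection bookkeeping: drop rules, overrides and identity", {
  # curated drop lists: 6 abiotic-model features, 8 full-model features
  expect_setequal(apply_curated_selection(model = "abiotic"),
                  c("salinity", "precipitation", "C", "Ca", "P", "carbonates"))
  expect_length(apply_curated_selection(model = "abiotic"), 6)
  expect_length(apply_curated_selection(model = "full"), 8)

  tab <- tiny_table(seed = 3)
  rep <- spearman_cluster_filter(tab, keep_policy = "manual",
                                 keep = c("C", "salinity"))
  # empty rules: identity on the filtered candidates
  sel <- select_features(rep, drop_below_noise = FALSE)
  expect_setequal(sel$retained, rep$kept)
  # unknown override is an error
  expect_error(select_features(rep, drop_below_noise = FALSE,
                               override_drop = "unobtainium"),
               "unobtainium")
  # with importance attached, below-noise features drop and noise never
  # survives selection
  frame <- build_model_frame(tab, features = rep$kept, include_competitors = FALSE)
  rep$importance <- noise_benchmark_importance(frame, rf_spec(num_trees = 40),
                                               seed = 2, n_repeats = 4)
  sel2 <- select_features(rep, drop_below_noise = TRUE, override_keep = "Ca")
  expect_false("random_noise" %in% sel2$retained)
  expect_true("Ca" %in% sel2$retained)
  expect_true(all(sel2$retained %in% rep$kept))
})
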