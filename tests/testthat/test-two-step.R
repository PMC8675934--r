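test_that("with a single species the two-step collapses onto the abiotic model", {
  cfg <- tiny_config(n_species = 1)
  tab <- simulate_community(cfg, seed = 1)$table
  two <- fit_two_step(tab, stage1_spec = model_spec("linear"),
                      stage2_spec = model_spec("linear"), seed = 3)
  rec <- tibble::as_tibble(tab)[setdiff(names(tab), species_names(tab))]
  p_two <- predict_two_step(two, rec)

  frame <- build_model_frame(tab, include_competitors = FALSE)
  abi <- fit_regressor(model_spec("linear"), frame)
  expect_equal(p_two$prediction, predict(abi, frame), tolerance = 1e-10)
})

test_that("prediction output is tidy long with one value per (record, species)", {
  tab <- tiny_table(seed = 2)
  two <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 30),
                      stage2_spec = rf_spec(num_trees = 30), seed = 1)
  rec <- tibble::as_tibble(tab)[1, setdiff(names(tab), species_names(tab))]
  p <- predict_two_step(two, rec)
  expect_equal(nrow(p), length(species_names(tab)))
  expect_setequal(p$species, species_names(tab))
  expect_named(p, c("plot", "subplot", "year", "species", "prediction"))

  p1 <- predict_stage1(two, rec)
  expect_equal(nrow(p1), length(species_names(tab)))
})

test_that("the prediction interface rejects observed abundances", {
  tab <- tiny_table(seed = 3)
  two <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 20),
                      stage2_spec = rf_spec(num_trees = 20), seed = 1)
  expect_error(predict_two_step(two, tibble::as_tibble(tab)),
               "abiotic data only")
  rec <- tibble::as_tibble(tab)[setdiff(names(tab), species_names(tab))]
  expect_error(predict_two_step(two, rec[setdiff(names(rec), "salinity")]),
               "salinity")
})

test_that("stage-1 outputs equal the competitor inputs bound into stage 2", {
  tab <- tiny_table(seed = 4)
  sp <- species_names(tab)
  two <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 30),
                      stage2_spec = rf_spec(num_trees = 30), seed = 2)
  rec <- tibble::as_tibble(tab)[1:5, setdiff(names(tab), sp)]
  p1 <- predict_stage1(two, rec)
  P <- commstack:::stage1_matrix(two, rec)
  expect_equal(p1$prediction, as.vector(P))

  # binding re-applies the focal zero-out rule on the predicted block
  frame2 <- build_model_frame(subset_communities(tab, 1:5))
  bound <- commstack:::bind_competitor_predictions(frame2, P)
  for (i in seq_along(sp)) {
    expect_true(all(bound[[paste0("comp_", sp[i])]][bound$focal == sp[i]] == 0))
    others <- bound$focal != sp[i]
    expect_true(all(bound[[paste0("comp_", sp[i])]][others] %in% P[, i]))
  }
})

test_that("feeding the training abiotic data reproduces in-sample stage-2 predictions", {
  tab <- tiny_table(seed = 5)
  two <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 40),
                      stage2_spec = rf_spec(num_trees = 40),
                      chaining = "in_sample", seed = 9)
  rec <- tibble::as_tibble(tab)[setdiff(names(tab), species_names(tab))]
  p_a <- predict_two_step(two, rec)
  p_b <- predict_two_step(two, rec)
  expect_identical(p_a$prediction, p_b$prediction)

  # manual stage-2 path: identical frame => bit-identical predictions
  frame1 <- build_model_frame(tab, include_competitors = FALSE)
  P1 <- matrix(predict(two$stage1, frame1), nrow(tab), length(species_names(tab)))
  frame2 <- commstack:::bind_competitor_predictions(build_model_frame(tab), P1)
  expect_identical(p_a$prediction, predict(two$stage2, frame2))
})

test_that("out-of-fold chaining is available and reproducible", {
  tab <- tiny_table(seed = 6)
  two_a <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 30),
                        stage2_spec = rf_spec(num_trees = 30),
                        chaining = "out_of_fold", seed = 4)
  two_b <- fit_two_step(tab, stage1_spec = rf_spec(num_trees = 30),
                        stage2_spec = rf_spec(num_trees = 30),
                        chaining = "out_of_fold", seed = 4)
  rec <- tibble::as_tibble(tab)[setdiff(names(tab), species_names(tab))]
  expect_identical(predict_two_step(two_a, rec)$prediction,
                   predict_two_step(two_b, rec)$prediction)
  # the linear family goes through the k-fold path
  two_l <- fit_two_step(tab, stage1_spec = model_spec("linear"),
                        stage2_spec = model_spec("linear"),
                        chaining = "out_of_fold", n_folds = 3, seed = 4)
  expect_s3_class(two_l, "two_step_model")
  expect_error(fit_two_step(tab, stage1_spec = model_spec("linear"),
                            stage2_spec = model_spec("linear"),
                            chaining = "out_of_fold", n_folds = 1),
               "folds")
})

test_that("the two-step model classifies absences better than the abiotic model", {
  tab <- simulate_community(seed = 1)$table
  spec <- model_spec("rf", num_trees = 100, max_depth = 18, min_node_size = 5,
                     seed = 1)
  fold <- spatial_block_kfold(tab, seed = 1)
  key <- paste(tab$plot, tab$subplot, sep = "\r")
  test <- fold$fold[match(key, paste(fold$plot, fold$subplot, sep = "\r"))] == 1
  s_two <- commstack:::fit_score(tab, pipeline_spec("two_step", spec = spec),
                                 !test, seed = 1)
  s_abi <- commstack:::fit_score(tab, pipeline_spec("abiotic", spec = spec),
                                 !test, seed = 1)
  expect_gt(zero_balanced_accuracy(s_two$observed, s_two$predicted),
            zero_balanced_accuracy(s_abi$observed, s_abi$predicted))
})

test_that("held-out two-step predictions track the ground-truth expectations", {
  sim <- simulate_community(seed = 6)
  tab <- sim$table
  fold <- spatial_block_kfold(tab, seed = 6)
  key <- paste(tab$plot, tab$subplot, sep = "\r")
  test <- fold$fold[match(key, paste(fold$plot, fold$subplot, sep = "\r"))] == 1
  two <- fit_two_step(subset_communities(tab, !test),
                      stage1_spec = rf_spec(num_trees = 80, max_depth = 16,
                                            min_node_size = 5),
                      stage2_spec = rf_spec(num_trees = 80, max_depth = 16,
                                            min_node_size = 5),
                      seed = 1)
  rec <- tibble::as_tibble(tab)[test, setdiff(names(tab), species_names(tab))]
  pred <- predict_two_step(two, rec)
  truth <- as.vector(sim$truth$expected[test, ])
  expect_gt(stats::cor(pred$prediction, truth, method = "spearman"), 0.5)
})
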