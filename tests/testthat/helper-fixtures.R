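# Shared fixtures: a small survey configuration for fast unit tests and a
# compact random-forest profile (fewer, depth-capped trees) used throughout
# the suite.

tiny_config <- function(n_species = 5, n_plots = 2, grid = c(3, 3),
                        years = 2015:2016,
                        precipitation = c(`2015` = 495, `2016` = 625)) {
  generator_config(n_plots = n_plots, grid = grid, years = years,
                   precipitation = precipitation, n_species = n_species)
}

tiny_table <- function(seed = 1, ...) {
  simulate_community(tiny_config(...), seed = seed)$table
}

rf_spec <- function(num_trees = 60, max_depth = 14, min_node_size = 10,
                    seed = 1, ...) {
  model_spec("rf", num_trees = num_trees, max_depth = max_depth,
             min_node_size = min_node_size, seed = seed, ...)
}

# Hand-written three-record CSV with a two-species pool, for parser tests.
write_mini_csv <- function(path, abundances = c("4,0", "0,2", "1,7")) {
  header <- "plot,subplot,year,x,y,pH,salinity,precipitation,AAA,BBB"
  rows <- c(
    sprintf("P1,S01,2015,0,0,8.1,2.5,495,%s", abundances[1]),
    sprintf("P1,S02,2015,1,0,7.9,3.1,495,%s", abundances[2]),
    sprintf("P1,S01,2016,0,0,8.1,2.5,625,%s", abundances[3])
  )
  writeLines(c(header, rows), path)
  path
}

mini_schema <- function() {
  list(species = c("AAA", "BBB"),
       abiotic = c("pH", "salinity", "precipitation"))
}

# Global pooled balanced accuracy of zero / non-zero classification at the
# 0.5 abundance threshold.
zero_balanced_accuracy <- function(observed, predicted) {
  mean(c(mean(predicted[observed == 0] < 0.5),
         mean(predicted[observed > 0] >= 0.5)))
}

# Spatial one-fold holdout R^2 of a pipeline, used by the heavier
# comparative tests.
holdout_r2 <- function(table, pipeline, seed) {
  spatial_cv_eval(table, pipeline, seed = seed, folds = 1)$medians$r2
}
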