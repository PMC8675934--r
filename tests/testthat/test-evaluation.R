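test_that("rmse and r-squared match hand arithmetic and honour their contracts", {
  expect_equal(rmse(c(0, 0, 3), c(0, 0, 0)), sqrt(3))
  expect_equal(rmse(1:5, 1:5), 0)
  y <- rnorm(20); yh <- rnorm(20)
  expect_equal(rmse(y, yh), rmse(yh, y))  # symmetric

  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 5)), -1)  # worse than the mean
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 20)), 0)
  expect_equal(rse(y, yh), 1 - r_squared(y, yh))

  expect_error(rmse(1:3, 1:4), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  expect_error(r_squared(1, 1), "at least 2")
})

test_that("spatial blocks partition the subplots and balance the folds", {
  tab <- simulate_community(seed = 1)$table
  for (s in 1:3) {
    fa <- spatial_block_kfold(tab, k = 4, block = c(3, 3), seed = s)
    # exactly one fold per subplot, all subplots covered
    expect_equal(nrow(fa), 9 * 36)
    expect_setequal(paste(fa$plot, fa$subplot),
                    unique(paste(tab$plot, tab$subplot)))
    # 6x6 grids cut by 3x3 windows: 4 blocks of 9 per plot, 36 blocks dealt
    # evenly over 4 folds
    expect_equal(as.vector(table(fa$fold)), rep(81L, 4))
  }
  # all years of a subplot share the fold by construction: the assignment
  # keys on (plot, subplot) only
  fa <- spatial_block_kfold(tab, seed = 1)
  expect_false(anyDuplicated(paste(fa$plot, fa$subplot)) > 0)

  expect_error(spatial_block_kfold(tiny_table(), k = 40), "blocks")
  expect_error(spatial_block_kfold(tab, k = 1), "at least 2")
})

test_that("per-species metrics score each slice and flag unscorable species", {
  obs <- c(1, 2, 3, 5, 5, 5)
  pred <- c(1, 2, 5, 4, 5, 6)
  sp <- c("A", "A", "A", "B", "B", "B")
  m <- per_species_metrics(obs, pred, sp)
  expect_equal(m$r2[m$species == "A"], r_squared(obs[1:3], pred[1:3]))
  expect_true(m$flagged[m$species == "B"])  # zero-variance observations
  expect_equal(m$rse, 1 - m$r2)

  # a single species reduces to the global metrics
  one <- per_species_metrics(obs[1:3], pred[1:3], rep("A", 3))
  expect_equal(one$rmse, rmse(obs[1:3], pred[1:3]))

  # species absent from the split is flagged, unknown labels error
  m2 <- per_species_metrics(obs, pred, sp, species_levels = c("A", "B", "C"))
  expect_true(m2$flagged[m2$species == "C"])
  expect_error(per_species_metrics(obs, pred, c(sp[-6], "Z"),
                                   species_levels = c("A", "B")),
               "unknown")
})

test_that("Moran's I matches its sampling theory on a grid", {
  coords <- expand.grid(x = 0:5, y = 0:5)
  # i.i.d. values: E[I] = -1/(n-1)
  set.seed(21)
  sims <- replicate(200, morans_i(rnorm(36), coords))
  expect_lt(abs(mean(sims) + 1 / 35), 0.02)

  # checkerboard under rook adjacency: perfect negative autocorrelation
  cb <- (-1)^(coords$x + coords$y)
  expect_lt(morans_i(cb, coords, scheme = "rook"), -0.99)
  # smooth gradient: strong positive autocorrelation among rook neighbours
  expect_gt(morans_i(coords$x + 0.01 * rnorm(36), coords, scheme = "rook"), 0.5)
  # inverse-distance weights dilute but preserve the sign
  expect_gt(morans_i(coords$x + 0.01 * rnorm(36), coords), 0.1)

  expect_error(morans_i(c(1, 2), coords[1:2, ]), "at least 3")
  expect_error(morans_i(rep(1, 36), coords), "zero-variance")
})

test_that("per-species Moran summaries skip constant fields", {
  tab <- tiny_table(seed = 2)
  msp <- species_morans_i(tab)
  expect_equal(nrow(msp), length(species_names(tab)))
  expect_true(all(msp$n_fields <= 4))  # 2 plots x 2 years
})

test_that("evaluation protocols are reproducible and their medians recomputable", {
  tab <- tiny_table(seed = 1)
  pipe <- pipeline_spec("abiotic", spec = rf_spec(num_trees = 25),
                        per_species = TRUE)
  a <- repeated_random_split_eval(tab, pipe, n_runs = 2, seed = 5)
  b <- repeated_random_split_eval(tab, pipe, n_runs = 2, seed = 5)
  expect_identical(a$records, b$records)
  g <- a$records[a$records$scope == "global", ]
  expect_equal(a$medians$r2, stats::median(g$r2))
  expect_equal(a$medians$rmse, stats::median(g$rmse))
  expect_true(any(a$records$scope == "species"))

  expect_error(repeated_random_split_eval(tab, pipe, n_runs = 0), "n_runs")
  expect_error(repeated_random_split_eval(tab, pipe, test_fraction = 1.2),
               "test_fraction")
})

test_that("per-species error spread is small for abundant species, wide for rare ones", {
  tab <- simulate_community(seed = 3)$table
  pipe <- pipeline_spec("two_step", spec = rf_spec(), per_species = TRUE)
  rd <- repeated_random_split_eval(tab, pipe, n_runs = 5, seed = 2)
  ps <- rd$records[rd$records$scope == "species" & !is.na(rd$records$rse), ]
  mu <- sort(colMeans(as.matrix(tibble::as_tibble(tab)[species_names(tab)])),
             decreasing = TRUE)
  abundant <- names(mu)[1:6]
  rare <- names(mu)[18:23]
  iqr_of <- function(set) {
    stats::median(vapply(split(ps$rse[ps$species %in% set],
                               ps$species[ps$species %in% set]),
                         stats::IQR, numeric(1)))
  }
  expect_lt(iqr_of(abundant), iqr_of(rare))
  expect_lt(stats::median(ps$rse[ps$species %in% abundant]),
            stats::median(ps$rse[ps$species %in% rare]))
})

test_that("leave-one-year-out holds each year out and trains on all others", {
  tab <- simulate_community(tiny_config(years = 2015:2019,
                                        precipitation = c(495, 625, 452, 560, 384)),
                            seed = 2)$table
  pipe <- pipeline_spec("abiotic", spec = model_spec("linear"))
  res <- leave_one_year_out_eval(tab, pipe)
  g <- res$records[res$records$scope == "global", ]
  expect_equal(nrow(g), 5)
  expect_setequal(g$year, 2015:2019)
  # held-out 2017: the training mask keeps both earlier and later years
  train <- tab$year != 2017
  expect_setequal(unique(tab$year[train]), c(2015, 2016, 2018, 2019))

  one_year <- subset_communities(tab, tab$year == 2015)
  expect_error(leave_one_year_out_eval(one_year, pipe), "2 distinct years")

  # dropping precipitation removes the only year-level feature
  res2 <- leave_one_year_out_eval(tab, pipe, drop_precipitation = TRUE)
  expect_equal(nrow(res2$records[res2$records$scope == "global", ]), 5)
})
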