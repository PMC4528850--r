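test_that("the single-dataset canonical grid yields exactly 192 distinct rows", {
  ds <- simulate_trees(n = 40, seed = 6)
  grid <- experiment_grid(transforms = "raw", sizes = NULL)
  expect_equal(knnbiomass:::.grid_cells(grid), 192L)
  res <- run_grid(ds, grid)
  expect_equal(nrow(res), 192L)
  expect_true(all(res$status == "ok"))
  desc <- paste(res$size, res$transform, res$subset, res$metric,
                res$weighting, res$k)
  expect_false(anyDuplicated(desc) > 0)
})

test_that("a degenerate one-cell grid equals the direct single-fit result", {
  ds <- simulate_trees(n = 50, seed = 10)
  grid <- experiment_grid(metrics = "chebyshev", weightings = "inv_d",
                          k = 5, variable_sets = list(all = tree_variables),
                          transforms = "raw", sizes = NULL)
  res <- run_grid(ds, grid)
  expect_equal(nrow(res), 1L)
  fit <- knn_biomass(ds, k = 5, metric = "chebyshev", weighting = "inv_d")
  expect_equal(res$syx, fit$criteria$syx)
  expect_equal(res$aic, fit$criteria$aic)
  expect_equal(res$r2_adj, fit$criteria$r2_adj)
})

test_that("grid runs are deterministic given the seed, including reduced series", {
  ds <- simulate_trees(n = 80, seed = 3)
  grid <- experiment_grid(metrics = c("euclidean", "chebyshev"),
                          weightings = "inv_d", k = c(1, 5),
                          variable_sets = predictor_sets()[c("dbh", "all")],
                          transforms = c("raw", "log"),
                          sizes = c(NA, 60, 40), seed = 11)
  r1 <- run_grid(ds, grid)
  r2 <- run_grid(ds, grid)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 3L * 2L * 2L * 2L * 1L * 2L)
  ## a different seed redraws the reduced series
  grid2 <- experiment_grid(metrics = "euclidean", weightings = "inv_d",
                           k = 1, variable_sets = list(all = tree_variables),
                           transforms = "raw", sizes = 40, seed = 12)
  grid3 <- grid2; grid3$seed <- 13L
  expect_false(identical(run_grid(ds, grid2)$syx, run_grid(ds, grid3)$syx))
})

test_that("infeasible cells fail in place and the accounting reconciles", {
  ds <- simulate_trees(n = 20, seed = 4)
  grid <- experiment_grid(metrics = "euclidean", weightings = "inv_d",
                          k = c(5, 11), variable_sets = list(dbh = "dbh"),
                          transforms = "raw", sizes = c(NA, 10, 50))
  res <- run_grid(ds, grid)
  expect_equal(nrow(res), 6L)
  s <- summary(res)
  expect_equal(s$ok + s$failed, nrow(res))
  ## k = 11 on the 10-record series and the whole size-50 arm are infeasible
  expect_equal(s$failed, 3L)
  expect_match(res$reason[res$size == "10" & res$k == 11], ">= n")
  expect_true(all(res$status[res$size == "50"] == "failed"))
  expect_true(all(is.na(res$syx[res$status == "failed"])))
  expect_true(all(is.finite(res$syx[res$status == "ok"])))
})

test_that("grid rank-1 by Syx equals rank-1 by AIC at common n and k_eff", {
  ds <- simulate_trees(n = 45, seed = 15)
  grid <- experiment_grid(weightings = c("inv_d", "inv_d2"),
                          k = c(1, 3, 5, 7),
                          variable_sets = list(all = tree_variables),
                          transforms = "raw", sizes = NULL)
  res <- run_grid(ds, grid)
  expect_equal(which.min(res$syx), which.min(res$aic))
  expect_equal(which.min(res$syx), which.min(res$bic))
  expect_equal(which.min(res$syx), which.max(res$r2_adj))
})

test_that("results tables export to CSV intact", {
  ds <- simulate_trees(n = 30, seed = 2)
  res <- run_grid(ds, experiment_grid(metrics = "euclidean",
                                      weightings = "inv_d", k = c(1, 3),
                                      variable_sets = list(dbh = "dbh"),
                                      transforms = "raw", sizes = NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_results(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$syx, res$syx)
})

test_that("the neighbour sweep is a pure function of its inputs", {
  ds <- simulate_trees(n = 60, seed = 20)
  sw1 <- neighbor_sweep(ds, k_values = 5)
  expect_equal(nrow(sw1), 1L)
  fit <- knn_biomass(ds, k = 5, metric = "chebyshev")
  expect_equal(sw1$syx, fit$criteria$syx)
  sw2 <- neighbor_sweep(ds)
  expect_identical(as.data.frame(sw2), as.data.frame(neighbor_sweep(ds)))
  expect_equal(sw2$k, c(1, 3, 5, 7, 9, 11))
  expect_error(neighbor_sweep(ds, k_values = c(5, 60)), "below")
})

test_that("on exactly log-linear data the allometric model beats the neighbours", {
  ds <- simulate_trees(n = 80, sigma = 0, seed = 17)
  cmp <- compare_to_allometry(ds)
  ## the regression is the true model: near-zero error, all gains negative
  expect_lt(cmp$sh_criteria_loo$syx, 1e-6)
  expect_true(all(cmp$gains < 0))
})

test_that("comparison gains equal individually computed gains for all metrics", {
  ds <- simulate_mixed_forest(n = 100, seed = 23)
  cmp <- compare_to_allometry(ds, k = 5, weighting = "inv_d")
  expect_named(cmp$gains, c("euclidean", "quadratic_euclidean",
                            "manhattan", "chebyshev"))
  for (m in names(cmp$gains)) {
    fit <- knn_biomass(ds, k = 5, metric = m, weighting = "inv_d")
    expect_equal(unname(cmp$gains[m]),
                 syx_gain(cmp$sh_criteria_loo, fit$criteria))
  }
  best <- names(which.min(vapply(cmp$knn_criteria, `[[`, numeric(1), "syx")))
  expect_equal(cmp$best_metric, best)
})
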