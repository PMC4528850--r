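test_that("weighted neighbour averages match hand computation", {
  expect_equal(weighted_estimate(c(10, 20), c(1, 2), "inv_d"), 40 / 3)
  expect_equal(weighted_estimate(c(10, 20), c(1, 2), "inv_d2"), 12)
  expect_equal(weighted_estimate(12.3, 0.7, "inv_d"), 12.3)
  expect_equal(weighted_estimate(12.3, 0.7, "inv_d2"), 12.3)
  ## equidistant neighbours reduce to the arithmetic mean
  expect_equal(weighted_estimate(c(3, 9, 6), rep(2.5, 3), "inv_d"), 6)
  ## zero-distance fallback: mean of the coincident neighbours only
  expect_equal(weighted_estimate(c(5, 11, 100), c(0, 0, 1), "inv_d2"), 8)
  expect_error(weighted_estimate(numeric(0), numeric(0)), "empty")
  expect_error(weighted_estimate(c(1, 2), c(1, -1)), "negative")
})

test_that("with two records each is the other's only neighbour", {
  df <- data.frame(dbh = c(5, 9), dm = c(1, 2), ht = c(4, 7),
                   hc = c(1, 2), da = c(0.7, 0.8), db = c(0.5, 0.6),
                   w = c(5, 7))
  fit <- knn_biomass(tree_data(df), k = 1, metric = "euclidean")
  expect_equal(fit$loocv$predicted, c(7, 5))
})

test_that("records with identical features swap biomass under LOOCV", {
  df <- data.frame(dbh = c(6, 6), dm = c(1, 1), ht = c(5, 5),
                   hc = c(1, 1), da = c(0.7, 0.7), db = c(0.5, 0.5),
                   w = c(5, 7))
  fit <- knn_biomass(tree_data(df), k = 1, metric = "chebyshev",
                     weighting = "inv_d2")
  expect_equal(fit$loocv$predicted, c(7, 5))
})

test_that("exact distance ties break toward the earlier record position", {
  ## query (record 1) at dbh 5; records 3 and 7 both at distance 1
  dbh <- c(5, 20, 6, 30, 40, 50, 4)
  df <- data.frame(dbh = dbh, dm = 1, ht = 9, hc = 1, da = 0.7, db = 0.5,
                   w = seq(10, 70, by = 10))
  fit <- knn_biomass(tree_data(df), variables = "dbh", k = 1,
                     metric = "euclidean")
  nb <- nearest_neighbors(fit, 1)
  expect_equal(nb$index, 3L)
  expect_equal(fit$loocv$predicted[1], 30)
})

test_that("LOOCV predictions match the brute-force oracle everywhere", {
  ds <- simulate_trees(n = 20, seed = 31)
  feat <- tree_features(ds, tree_variables)
  for (m in c("euclidean", "quadratic_euclidean", "manhattan", "chebyshev"))
    for (wgt in c("inv_d", "inv_d2"))
      for (k in c(1, 3, 5)) {
        fit <- knn_biomass(ds, k = k, metric = m, weighting = wgt)
        expect_equal(fit$loocv$predicted,
                     oracle_loocv(feat$x, feat$y, k, m, wgt),
                     tolerance = 1e-12,
                     label = paste(m, wgt, k))
      }
})

test_that("neighbour sets match an exhaustive-sort oracle", {
  ds <- simulate_trees(n = 30, seed = 77)
  feat <- tree_features(ds, tree_variables)
  for (m in c("euclidean", "chebyshev"))
    for (k in c(1, 3, 5)) {
      fit <- knn_biomass(ds, k = k, metric = m)
      for (i in c(1, 15, 30)) {
        d <- vapply(seq_len(30), function(j)
          oracle_dist(feat$x[i, ], feat$x[j, ], m), numeric(1))
        d[i] <- Inf
        expect_equal(nearest_neighbors(fit, i)$index,
                     order(d, seq_len(30))[seq_len(k)])
      }
    }
})

test_that("every prediction is a convex combination of neighbour biomass", {
  ds <- simulate_trees(n = 40, seed = 5)
  fit <- knn_biomass(ds, k = 5, metric = "manhattan")
  for (i in seq_len(40)) {
    nb <- nearest_neighbors(fit, i)
    expect_gte(fit$loocv$predicted[i], min(nb$w) - 1e-12)
    expect_lte(fit$loocv$predicted[i], max(nb$w) + 1e-12)
  }
})

test_that("a record's own biomass never leaks into its prediction", {
  ds <- simulate_trees(n = 25, seed = 13)
  fit <- knn_biomass(ds, k = 3, metric = "euclidean")
  for (i in c(2, 11, 25)) {
    pert <- as.data.frame(ds)
    pert$w[i] <- pert$w[i] * 50
    fit2 <- knn_biomass(tree_data(pert), k = 3, metric = "euclidean")
    expect_equal(fit2$loocv$predicted[i], fit$loocv$predicted[i])
  }
})

test_that("record order does not change the multiset of LOOCV pairs", {
  ds <- simulate_trees(n = 30, seed = 8)
  fit <- knn_biomass(ds, k = 5, metric = "chebyshev")
  set.seed(1)
  perm <- sample.int(30)
  shuf <- as.data.frame(ds)[perm, ]
  fit2 <- knn_biomass(tree_data(shuf), k = 5, metric = "chebyshev")
  o1 <- order(fit$loocv$actual, fit$loocv$predicted)
  o2 <- order(fit2$loocv$actual, fit2$loocv$predicted)
  expect_equal(fit$loocv$actual[o1], fit2$loocv$actual[o2])
  expect_equal(fit$loocv$predicted[o1], fit2$loocv$predicted[o2],
               tolerance = 1e-12)
})

test_that("with coincident features and k = n - 1 predictions are leave-one-out means", {
  df <- data.frame(dbh = 6, dm = 1, ht = 5, hc = 1, da = 0.7, db = 0.5,
                   w = c(2, 4, 6, 8))
  fit <- knn_biomass(tree_data(df), k = 3, metric = "euclidean")
  expect_equal(fit$loocv$predicted, c(6, 16 / 3, 14 / 3, 4))
})

test_that("log-scale fitting back-transforms for the original-scale criteria", {
  ds <- simulate_trees(n = 50, seed = 21)
  fit <- knn_biomass(ds, k = 5, metric = "euclidean", use_log = TRUE)
  expect_equal(fit$loocv$predicted,
               exp(fit$loocv$predicted_transformed))
  expect_equal(fit$criteria$n, 50)
  expect_s3_class(fit$criteria_transformed, "criteria_set")
  expect_equal(residuals(fit, scale = "transformed"),
               fit$loocv$actual_transformed - fit$loocv$predicted_transformed)
})

test_that("prediction at a training point with k = 1 returns that tree's biomass", {
  ds <- toy_trees(8)
  fit <- knn_biomass(ds, k = 1, metric = "euclidean")
  new <- as.data.frame(ds)[3, tree_variables]
  expect_equal(predict(fit, new), ds$w[3])
})

test_that("neighbour counts are validated and non-canonical values warn", {
  ds <- toy_trees(8)
  expect_warning(knn_biomass(ds, k = 4), "canonical")
  expect_error(knn_biomass(ds, k = 8), "n - 1")
  expect_silent(knn_biomass(ds, k = 7))
})
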