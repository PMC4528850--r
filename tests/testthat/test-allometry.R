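truth <- c(a = -1.390796, b = 1.051491, c = 1.084280)

test_that("noise-free log-linear data recovers the generating coefficients", {
  ds <- simulate_trees(n = 60, sigma = 0, seed = 11)
  fit <- schumacher_hall(ds)
  expect_equal(coef(fit), truth, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("a constant response yields a pure-intercept fit", {
  df <- data.frame(dbh = c(4, 8, 12, 16), dm = 1, ht = c(3, 5, 8, 6),
                   hc = 1, da = 0.7, db = 0.5, w = exp(5))
  fit <- schumacher_hall(tree_data(df))
  expect_equal(unname(coef(fit)), c(5, 0, 0), tolerance = 1e-10)
})

test_that("prediction evaluates the fitted law with optional back-transform", {
  ds <- simulate_trees(n = 50, sigma = 0, seed = 3)
  fit <- schumacher_hall(ds)
  new <- data.frame(dbh = 10, ht = 8)
  ## direct evaluation of the generating coefficients
  expect_equal(predict(fit, new, back_transform = FALSE), 3.2850483768,
               tolerance = 1e-6)
  expect_equal(round(predict(fit, new), 2), 26.71)
  expect_equal(predict(fit, data.frame(dbh = 1, ht = 1),
                       back_transform = FALSE),
               unname(coef(fit)["a"]), tolerance = 1e-9)
})

test_that("the Baskerville correction is exactly the lognormal factor", {
  ds <- simulate_trees(n = 80, sigma = 0.3, seed = 6)
  fit <- schumacher_hall(ds)
  new <- data.frame(dbh = c(5, 12), ht = c(4, 9))
  expect_equal(predict(fit, new, correction = "baskerville"),
               predict(fit, new) * exp(fit$sigma2 / 2))
})

test_that("OLS residuals are orthogonal to the design and centred", {
  ds <- simulate_trees(n = 100, sigma = 0.3, seed = 14)
  fit <- schumacher_hall(ds)
  e <- fit$residuals
  scale_rss <- sqrt(sum(e^2))
  expect_lt(abs(sum(e)), 1e-8 * scale_rss)
  expect_lt(abs(sum(e * log(ds$dbh))), 1e-7 * scale_rss)
  ## prediction at the ln-scale centroid equals the mean response
  cen <- data.frame(dbh = exp(mean(log(ds$dbh))), ht = exp(mean(log(ds$ht))))
  expect_equal(predict(fit, cen, back_transform = FALSE),
               mean(log(ds$w)), tolerance = 1e-9)
})

test_that("rank-deficient designs are refused with the offending column named", {
  df <- data.frame(dbh = 7, dm = 1, ht = c(3, 5, 8, 6), hc = 1,
                   da = 0.7, db = 0.5, w = c(5, 9, 14, 11))
  expect_error(schumacher_hall(tree_data(df)), "ln\\(dbh\\) is constant")
  df2 <- data.frame(dbh = c(4, 8, 12, 16), dm = 1, ht = c(4, 8, 12, 16) * 0.5,
                    hc = 1, da = 0.7, db = 0.5, w = c(2, 9, 20, 38))
  expect_error(schumacher_hall(tree_data(df2)), "collinear")
})

test_that("leave-one-out predictions obey the OLS hat-matrix identity", {
  ds <- simulate_trees(n = 40, sigma = 0.3, seed = 19)
  fit <- schumacher_hall(ds)
  loo <- predict(fit, loo = TRUE, back_transform = FALSE)
  ## brute force: refit without each record
  for (i in c(1, 17, 40)) {
    sub <- tree_data(as.data.frame(ds)[-i, ])
    f2 <- schumacher_hall(sub)
    expect_equal(loo[i],
                 predict(f2, data.frame(dbh = ds$dbh[i], ht = ds$ht[i]),
                         back_transform = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Durbin-Watson statistic matches hand cases and stays in [0, 4]", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(rep(0.37, 6)), 0)
  set.seed(2)
  for (i in 1:20) {
    dw <- durbin_watson(rnorm(30))
    expect_gte(dw, 0); expect_lte(dw, 4)
  }
  ## near 2 on independent residuals
  set.seed(3)
  dws <- replicate(200, {
    x <- rnorm(200); y <- rnorm(200)
    durbin_watson(residuals(lm(y ~ x)))
  })
  expect_lt(abs(mean(dws) - 2), 0.1)
  expect_error(durbin_watson(c(0, 0, 0)), "zero")
})

test_that("diagnostics agree with the reference implementations", {
  ds <- simulate_trees(n = 120, sigma = 0.3, seed = 8)
  fit <- schumacher_hall(ds)
  d <- sh_diagnostics(fit)
  expect_equal(d$durbin_watson$statistic, durbin_watson(fit$residuals))
  expect_equal(d$durbin_watson$statistic,
               unname(lmtest::dwtest(fit$lm)$statistic))
  expect_equal(d$shapiro_wilk$statistic,
               unname(stats::shapiro.test(fit$residuals)$statistic))
  ## White statistic is the studentized LM statistic of the auxiliary design
  bt <- lmtest::bptest(fit$lm, ~ ldbh * lht + I(ldbh^2) + I(lht^2),
                       data = data.frame(ldbh = fit$data$ldbh,
                                         lht = fit$data$lht))
  expect_equal(d$white$statistic, unname(bt$statistic), tolerance = 1e-8)
  expect_equal(d$white$df, unname(bt$parameter))
  expect_gt(d$shapiro_wilk$statistic, 0)
  expect_lte(d$shapiro_wilk$statistic, 1)
  expect_gte(d$white$statistic, 0)
})

test_that("simulate() draws reproducible lognormal responses around the fit", {
  ds <- simulate_trees(n = 50, sigma = 0.25, seed = 44)
  fit <- schumacher_hall(ds)
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(50L, 3L))
  expect_true(all(s1 > 0))
})
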