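#' Fit the Schumacher-Hall log-linear allometric model
#'
#' Ordinary-least-squares fit of the classic biomass allometry
#' \deqn{\ln(w) = a + b \ln(dbh) + c \ln(ht) + e_i,}
#' the standard regression benchmark for individual-tree biomass and volume.
#' The fit is carried out on the natural-log scale via [stats::lm()];
#' residuals are stored on that scale.
#'
#' @param data A [tree_data] object; on the raw scale `dbh`, `ht` and `w`
#'   must be strictly positive, or an already log-transformed dataset may be
#'   passed.
#' @return Object of class `"schumacher_hall"`: coefficients `a`, `b`, `c`,
#'   ln-scale residuals and fitted values, the residual variance estimate
#'   `sigma2` (RSS / (n - 3)), and the underlying `lm` fit.  Methods:
#'   `coef`, `print`, `summary`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @examples
#' ds <- simulate_trees(n = 100, sigma = 0.2, seed = 7)
#' fit <- schumacher_hall(ds)
#' coef(fit)
#' predict(fit, data.frame(dbh = 10, ht = 8))
#' @export
schumacher_hall <- function(data) {
  stopifnot(inherits(data, "tree_data"))
  n <- nrow(data)
  if (n < 4L)
    stop("need at least 4 trees to fit three coefficients", call. = FALSE)
  if (attr(data, "transform") == "log") {
    lw <- data$w; ldbh <- data$dbh; lht <- data$ht
  } else {
    for (v in c("dbh", "ht", "w")) {
      bad <- which(data[[v]] <= 0)
      if (length(bad))
        stop("non-positive '", v, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    lw <- log(data$w); ldbh <- log(data$dbh); lht <- log(data$ht)
  }
  if (stats::var(ldbh) == 0)
    stop("design is rank deficient: ln(dbh) is constant", call. = FALSE)
  if (stats::var(lht) == 0)
    stop("design is rank deficient: ln(ht) is constant", call. = FALSE)
  df_fit <- data.frame(lw = lw, ldbh = ldbh, lht = lht)
  fit <- stats::lm(lw ~ ldbh + lht, data = df_fit)
  if (fit$qr$rank < 3L)
    stop("design is rank deficient: ln(dbh) and ln(ht) are collinear",
         call. = FALSE)
  cf <- stats::coef(fit)
  names(cf) <- c("a", "b", "c")
  e <- stats::residuals(fit)
  structure(list(
    call = match.call(),
    coefficients = cf,
    residuals = unname(e),
    fitted_log = unname(stats::fitted(fit)),
    sigma2 = sum(e^2) / (n - 3L),
    n = n,
    data = list(dbh = data$dbh, ht = data$ht, w = data$w,
                ldbh = ldbh, lht = lht, lw = lw,
                transform = attr(data, "transform")),
    lm = fit
  ), class = "schumacher_hall")
}

#' @export
coef.schumacher_hall <- function(object, ...) object$coefficients

#' @export
residuals.schumacher_hall <- function(object,
                                      scale = c("log", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "log") object$residuals
  else exp(object$data$lw) - exp(object$fitted_log)
}

#' @export
fitted.schumacher_hall <- function(object,
                                   scale = c("original", "log"), ...) {
  scale <- match.arg(scale)
  if (scale == "log") object$fitted_log else exp(object$fitted_log)
}

#' Predict biomass from a fitted Schumacher-Hall model
#'
#' Evaluates \eqn{a + b \ln(dbh) + c \ln(ht)} and, by default, exponentiates
#' back to the biomass scale.  Plain exponentiation of a log-scale mean
#' underestimates the conditional mean under lognormal error; the
#' Baskerville correction multiplies the back-transformed prediction by
#' \eqn{\exp(s^2/2)}, with \eqn{s^2} the residual variance.  The correction
#' is opt-in: the uncorrected form is how the model is usually applied in
#' practice, and the choice is left explicit.
#'
#' @param object A fitted `schumacher_hall` model.
#' @param newdata Data frame with columns `dbh` and `ht` (measurement
#'   units); omit to predict at the training records.
#' @param back_transform Exponentiate the ln-scale prediction?
#' @param correction `"none"` or `"baskerville"` (only meaningful with
#'   `back_transform = TRUE`).
#' @param loo With `newdata = NULL`, return leave-one-out predictions for
#'   the training records (exact OLS identity
#'   \eqn{\hat y_{(i)} = y_i - e_i/(1 - h_{ii})} on the ln scale) instead of
#'   in-sample fitted values.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.schumacher_hall <- function(object, newdata = NULL,
                                    back_transform = TRUE,
                                    correction = c("none", "baskerville"),
                                    loo = FALSE, ...) {
  correction <- match.arg(correction)
  if (is.null(newdata)) {
    pred_log <- if (loo) {
      h <- stats::lm.influence(object$lm, do.coef = FALSE)$hat
      object$data$lw - object$residuals / (1 - h)
    } else object$fitted_log
  } else {
    if (loo) stop("'loo' applies only to the training records", call. = FALSE)
    miss <- setdiff(c("dbh", "ht"), names(newdata))
    if (length(miss))
      stop("newdata lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(newdata$dbh <= 0) || any(newdata$ht <= 0))
      stop("'dbh' and 'ht' must be strictly positive", call. = FALSE)
    cf <- object$coefficients
    pred_log <- cf["a"] + cf["b"] * log(newdata$dbh) +
      cf["c"] * log(newdata$ht)
  }
  pred_log <- unname(pred_log)
  if (!back_transform) return(pred_log)
  out <- exp(pred_log)
  if (correction == "baskerville") out <- out * exp(object$sigma2 / 2)
  out
}

#' @export
print.schumacher_hall <- function(x, digits = 6, ...) {
  cf <- x$coefficients
  cat("Schumacher-Hall allometric model (OLS on the ln scale)\n")
  cat(sprintf("  ln(w) = %s + %s ln(dbh) + %s ln(ht),  n = %d\n",
              format(cf["a"], digits = digits),
              format(cf["b"], digits = digits),
              format(cf["c"], digits = digits), x$n))
  cat(sprintf("  residual SD (ln scale) = %s\n",
              format(sqrt(x$sigma2), digits = 4)))
  invisible(x)
}

#' @export
summary.schumacher_hall <- function(object, ...) {
  ls <- summary(object$lm)
  rownames(ls$coefficients) <- c("a (intercept)", "b (ln dbh)", "c (ln ht)")
  crit_log <- fit_criteria(object$data$lw, object$fitted_log, n_params = 3L)
  crit_orig <- fit_criteria(exp(object$data$lw), exp(object$fitted_log),
                            n_params = 3L)
  out <- list(coefficients = ls$coefficients, sigma = sqrt(object$sigma2),
              n = object$n, criteria_log = crit_log,
              criteria_original = crit_orig)
  class(out) <- "summary.schumacher_hall"
  out
}

#' @export
print.summary.schumacher_hall <- function(x, digits = 4, ...) {
  cat("Schumacher-Hall allometric model (OLS on the ln scale), n =",
      x$n, "\n\n")
  stats::printCoefmat(x$coefficients, digits = 6)
  cat("\nResidual SD (ln scale):", format(x$sigma, digits = digits), "\n")
  cat("\nCriteria, ln scale (k = 3):\n"); print(x$criteria_log, digits)
  cat("Criteria, original scale, back-transformed fit (k = 3):\n")
  print(x$criteria_original, digits)
  invisible(x)
}

#' Simulate biomass from a fitted allometric model
#'
#' Draws new biomass responses at the training trees' sizes from the fitted
#' law with lognormal error: \eqn{w^{sim} = \exp(a + b\ln dbh + c\ln ht +
#' \epsilon)}, \eqn{\epsilon \sim N(0, s^2)}.
#'
#' @param object A fitted `schumacher_hall` model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (caller's RNG stream is preserved).
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated biomass vector per
#'   column.
#' @export
simulate.schumacher_hall <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted_log
  s <- sqrt(object$sigma2)
  sims <- with_seed(seed, replicate(nsim, exp(mu + stats::rnorm(object$n, 0, s)),
                                    simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residual plots for a Schumacher-Hall fit
#'
#' Observed versus fitted biomass (original scale, 1:1 line) and ln-scale
#' residuals against fitted values.
#'
#' @param x A fitted `schumacher_hall` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.schumacher_hall <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(fitted(x), exp(x$data$lw), xlab = "Fitted biomass",
                 ylab = "Observed biomass", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$fitted_log, x$residuals, xlab = "Fitted ln(w)",
                 ylab = "Residual (ln scale)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Durbin-Watson statistic of a residual sequence
#'
#' \deqn{DW = \sum_{t=2}^n (e_t - e_{t-1})^2 / \sum_t e_t^2,}
#' always in \[0, 4\], near 2 for serially independent residuals.  The
#' sequence is taken in the order given (record order, for a fitted model).
#'
#' @param e Numeric residual vector, length at least 2, not all zero.
#' @return The DW statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' @export
durbin_watson <- function(e) {
  if (length(e) < 2L) stop("need at least 2 residuals", call. = FALSE)
  if (!all(is.finite(e))) stop("non-finite residual", call. = FALSE)
  s2 <- sum(e^2)
  if (s2 == 0) stop("all residuals are zero; DW is undefined", call. = FALSE)
  sum(diff(e)^2) / s2
}

#' White's heteroscedasticity test
#'
#' Regresses squared residuals on the explanatory variables, their squares
#' and their cross-products; the test statistic is \eqn{n R^2} of that
#' auxiliary regression, referred to a chi-squared distribution with as many
#' degrees of freedom as the auxiliary regression has (non-aliased) slope
#' terms.  Large values indicate that the residual variance depends on the
#' predictors, i.e. heteroscedasticity.
#'
#' @param e Residual vector.
#' @param x Numeric design matrix of explanatory variables (without
#'   intercept), rows matching `e`.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
white_test <- function(e, x) {
  x <- as.matrix(x)
  if (nrow(x) != length(e))
    stop("'x' rows must match residual length", call. = FALSE)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  aux <- x
  for (j in seq_len(p))
    for (l in j:p) {
      aux <- cbind(aux, x[, j] * x[, l])
      colnames(aux)[ncol(aux)] <- paste0(colnames(x)[j], ".", colnames(x)[l])
    }
  ## drop duplicated auxiliary columns (e.g. dummies whose square repeats)
  aux <- aux[, !duplicated(t(aux)), drop = FALSE]
  n <- length(e)
  if (n < ncol(aux) + 2L)
    stop("too few observations for the auxiliary regression", call. = FALSE)
  fit <- stats::lm(I(e^2) ~ aux)
  df <- fit$qr$rank - 1L
  r2 <- summary(fit)$r.squared
  stat <- n * r2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Regression-assumption diagnostics for a Schumacher-Hall fit
#'
#' The three textbook residual checks behind log-linear biomass allometry:
#' Shapiro-Wilk for normality, White's test for heteroscedasticity, and
#' Durbin-Watson for serial correlation of residuals taken in record order.
#' Statistics and p-values are reported without a verdict; what constitutes
#' an acceptable departure is left to the analyst.  The Durbin-Watson
#' p-value comes from [lmtest::dwtest()] on the underlying `lm` fit.
#'
#' @param object A fitted `schumacher_hall` model.
#' @return Object of class `"sh_diagnostics"`: list with components
#'   `shapiro_wilk` (`statistic`, `p_value`), `white` (`statistic`, `df`,
#'   `p_value`) and `durbin_watson` (`statistic`, `p_value`).
#' @examples
#' ds <- simulate_trees(n = 120, seed = 3)
#' sh_diagnostics(schumacher_hall(ds))
#' @export
sh_diagnostics <- function(object) {
  stopifnot(inherits(object, "schumacher_hall"))
  e <- object$residuals
  sw <- stats::shapiro.test(e)
  wt <- white_test(e, cbind(ldbh = object$data$ldbh,
                            lht = object$data$lht))
  dw <- lmtest::dwtest(object$lm, alternative = "two.sided")
  structure(list(
    shapiro_wilk = list(statistic = unname(sw$statistic),
                        p_value = sw$p.value),
    white = wt,
    durbin_watson = list(statistic = unname(dw$statistic),
                         p_value = dw$p.value)
  ), class = "sh_diagnostics")
}

#' @export
print.sh_diagnostics <- function(x, digits = 4, ...) {
  cat("Residual diagnostics (ln-scale OLS residuals)\n")
  cat(sprintf("  Shapiro-Wilk  W  = %s  (p = %s)\n",
              format(x$shapiro_wilk$statistic, digits = digits),
              format.pval(x$shapiro_wilk$p_value, digits = digits)))
  cat(sprintf("  White         LM = %s  (df = %d, p = %s)\n",
              format(x$white$statistic, digits = digits), x$white$df,
              format.pval(x$white$p_value, digits = digits)))
  cat(sprintf("  Durbin-Watson DW = %s  (p = %s)\n",
              format(x$durbin_watson$statistic, digits = digits),
              format.pval(x$durbin_watson$p_value, digits = digits)))
  invisible(x)
}
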