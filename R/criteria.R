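#' Model-selection criteria for paired actual/predicted biomass
#'
#' Computes the five goodness-of-fit criteria used to rank biomass models,
#' uniformly for regression fits and cross-validated nearest-neighbour
#' predictions.  With residuals \eqn{e_i = w_i - \hat w_i}, RSS
#' \eqn{= \sum e_i^2} and \eqn{k} = `n_params`:
#' \deqn{R^2 = 1 - RSS / \sum (w_i - \bar w)^2}
#' \deqn{R^2_{adj} = 1 - \frac{n - 1}{n - k} (1 - R^2)}
#' \deqn{S_{yx} = \sqrt{RSS / (n - k)}}
#' and, with \eqn{k_{eff} = k + 1} (one extra degree of freedom for the
#' residual variance),
#' \deqn{AIC = n \ln(RSS/n) + 2 k_{eff}}
#' \deqn{AICc = n \ln(RSS/n) + 2 k_{eff} \, n / (n - k_{eff} - 1)}
#' \deqn{BIC = n \ln(RSS/n) + \ln(n) \, k_{eff}.}
#'
#' AICc is the small-sample form of AIC, conventionally preferred when
#' `n / k_eff < 40`; both are always reported and the returned
#' `aicc_recommended` flag records whether the rule of thumb applies, so no
#' silent criterion switching takes place.  \eqn{R^2} can be negative for a
#' model worse than the mean predictor and is deliberately not clamped.
#'
#' @param actual Observed biomass values.
#' @param predicted Predicted biomass values, same length and scale.
#' @param n_params Parameter count `k` of the model.  For the log-linear
#'   allometric model this is 3 (intercept and two slopes); for a
#'   nearest-neighbour configuration the package uses the number of
#'   predictor variables as a degrees-of-freedom proxy (the method has no
#'   fitted coefficients), which callers may override.
#' @return Object of class `"criteria_set"`: list with `r2`, `r2_adj`,
#'   `syx`, `aic`, `aicc`, `bic`, `k_params`, `k_eff`, `n`, `rss`,
#'   `residuals`, `aicc_recommended`.
#' @examples
#' set.seed(1)
#' w <- rlnorm(30, 3, 0.8)
#' fit_criteria(w, w * exp(rnorm(30, 0, 0.1)), n_params = 2)
#' @export
fit_criteria <- function(actual, predicted, n_params) {
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have the same length", call. = FALSE)
  if (!all(is.finite(actual)) || !all(is.finite(predicted)))
    stop("non-finite value in 'actual' or 'predicted'", call. = FALSE)
  if (!is.numeric(n_params) || length(n_params) != 1L ||
      n_params != round(n_params) || n_params < 1)
    stop("'n_params' must be a single positive whole number", call. = FALSE)
  n <- length(actual)
  if (n < n_params + 2L)
    stop("need n >= n_params + 2 (", n_params + 2L, "), got n = ", n,
         call. = FALSE)
  e <- actual - predicted
  rss <- sum(e^2)
  tss <- sum((actual - mean(actual))^2)
  if (tss == 0)
    stop("response variance is zero; R2 is undefined", call. = FALSE)
  k <- as.integer(n_params)
  k_eff <- k + 1L
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (n - 1) / (n - k) * (1 - r2)
  syx <- sqrt(rss / (n - k))
  if (rss == 0) {
    warning("zero residual sum of squares; information criteria are -Inf",
            call. = FALSE)
    aic <- aicc <- bic <- -Inf
  } else {
    dev <- n * log(rss / n)
    aic <- dev + 2 * k_eff
    aicc <- if (n > k_eff + 1L) dev + 2 * k_eff * n / (n - k_eff - 1) else Inf
    bic <- dev + log(n) * k_eff
  }
  structure(list(r2 = r2, r2_adj = r2_adj, syx = syx,
                 aic = aic, aicc = aicc, bic = bic,
                 k_params = k, k_eff = k_eff, n = n, rss = rss,
                 residuals = e,
                 aicc_recommended = n / k_eff < 40),
            class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, digits = 4, ...) {
  cat(sprintf(
    "  R2 = %s  R2adj = %s  Syx = %s\n  AIC = %s  AICc = %s%s  BIC = %s  (n = %d, k = %d)\n",
    format(x$r2, digits = digits), format(x$r2_adj, digits = digits),
    format(x$syx, digits = digits), format(x$aic, digits = digits),
    format(x$aicc, digits = digits),
    if (x$aicc_recommended) "*" else "",
    format(x$bic, digits = digits), x$n, x$k_params))
  if (x$aicc_recommended)
    cat("  (* small sample: n/k_eff < 40, AICc preferred over AIC)\n")
  invisible(x)
}

#' @export
as.data.frame.criteria_set <- function(x, ...) {
  data.frame(r2 = x$r2, r2_adj = x$r2_adj, syx = x$syx, aic = x$aic,
             aicc = x$aicc, bic = x$bic, k_params = x$k_params,
             k_eff = x$k_eff, n = x$n)
}

.syx_of <- function(x) {
  if (inherits(x, "criteria_set")) x$syx
  else if (is.numeric(x) && length(x) == 1L) x
  else stop("expected a criteria_set or a single Syx value", call. = FALSE)
}

#' Percent reduction in standard error of estimate
#'
#' The headline comparison statistic: by how many percent a candidate
#' model's Syx undercuts a reference model's,
#' \deqn{100 (S_{ref} - S_{cand}) / S_{ref}.}
#' Positive values mean the candidate is more accurate; both Syx values must
#' be on the same response scale.
#'
#' @param reference,candidate `criteria_set` objects or bare Syx values.
#' @return Gain in percent (can be negative).
#' @examples
#' syx_gain(10.452, 8.727)  # ~16.5 %
#' @export
syx_gain <- function(reference, candidate) {
  s_ref <- .syx_of(reference)
  s_cand <- .syx_of(candidate)
  if (s_ref <= 0)
    stop("reference Syx must be positive; gain is undefined", call. = FALSE)
  100 * (s_ref - s_cand) / s_ref
}

#' Rank competing models by one selection criterion
#'
#' Orders a collection of criteria sets best-first: ascending for `syx`,
#' `aic`, `aicc` and `bic`, descending for `r2_adj`.  Ties keep input
#' order.  Criteria computed on different sample sizes are not strictly
#' comparable; mixed `n` triggers a warning, not an error.
#'
#' @param sets Named (or unnamed) list of `criteria_set` objects, length
#'   at least 2.
#' @param criterion One of `"syx"`, `"aic"`, `"aicc"`, `"bic"`, `"r2_adj"`.
#' @return Data frame with columns `model`, `value`, `rank`, ordered
#'   best-first.
#' @export
rank_models <- function(sets, criterion = c("syx", "aic", "aicc", "bic",
                                            "r2_adj")) {
  criterion <- match.arg(criterion)
  if (!is.list(sets) || length(sets) < 2L)
    stop("'sets' must be a list of at least two criteria sets",
         call. = FALSE)
  if (!all(vapply(sets, inherits, logical(1), "criteria_set")))
    stop("every element of 'sets' must be a criteria_set", call. = FALSE)
  ns <- vapply(sets, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1L)
    warning("criteria sets have different n; ranks may not be comparable",
            call. = FALSE)
  v <- vapply(sets, `[[`, numeric(1), criterion)
  ord <- order(if (criterion == "r2_adj") -v else v)  # stable: ties keep input order
  nm <- names(sets)
  if (is.null(nm)) nm <- as.character(seq_along(sets))
  out <- data.frame(model = nm[ord], value = v[ord],
                    rank = seq_along(ord), row.names = NULL)
  names(out)[2L] <- criterion
  out
}
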