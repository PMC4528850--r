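#' Inverse-distance weighted neighbour average
#'
#' Combines the biomass values of a set of neighbours into a single
#' prediction using weights \eqn{u_i = 1/d_i} (`"inv_d"`) or
#' \eqn{u_i = 1/d_i^2} (`"inv_d2"`):
#' \deqn{\hat w = \sum u_i y_i / \sum u_i.}
#' When one or more neighbours sit at distance zero the weights are
#' undefined; the prediction is then the unweighted mean of the
#' zero-distance neighbours' biomass, which is the limit of the weighted
#' mean as those distances shrink to zero.
#'
#' @param w Numeric vector of neighbour biomass values.
#' @param distance Numeric vector of neighbour distances, same length,
#'   non-negative.
#' @param weighting `"inv_d"` or `"inv_d2"`.
#' @return The predicted biomass, a single number lying between
#'   `min(w)` and `max(w)`.
#' @examples
#' weighted_estimate(c(10, 20), c(1, 2), "inv_d")   # 13.33
#' weighted_estimate(c(10, 20), c(1, 2), "inv_d2")  # 12
#' @export
weighted_estimate <- function(w, distance, weighting = c("inv_d", "inv_d2")) {
  weighting <- match.arg(weighting)
  if (!length(w)) stop("empty neighbour set", call. = FALSE)
  if (length(w) != length(distance))
    stop("'w' and 'distance' must have the same length", call. = FALSE)
  if (any(distance < 0)) stop("negative distance", call. = FALSE)
  if (any(distance == 0)) return(mean(w[distance == 0]))
  u <- if (weighting == "inv_d") 1 / distance else 1 / distance^2
  sum(u * w) / sum(u)
}

## Leave-one-out predictions given a precomputed distance matrix.  Ties at
## the k-th neighbour are broken by ascending record position (order() with
## radix sort is stable).
.loocv_from_dist <- function(D, y, k, weighting) {
  n <- length(y)
  diag(D) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    weighted_estimate(y[nb], D[i, nb], weighting)
  }, numeric(1))
}

.canonical_k <- c(1L, 3L, 5L, 7L, 9L, 11L)

#' Nearest-neighbour tree biomass estimator
#'
#' Fits an instance-based biomass model: the training records themselves are
#' the model, and a tree's biomass is predicted as the inverse-distance
#' weighted mean of the biomass of its `k` nearest neighbours in predictor
#' space.  Accuracy is assessed by leave-one-out cross-validation (LOOCV):
#' each record is predicted from all other records, never from itself, and
#' the model-selection criteria stored in the fit are computed from those
#' out-of-sample predictions.
#'
#' With `use_log = TRUE` both predictors and response are natural-log
#' transformed before distances and neighbour averages are computed;
#' predictions are made on the log scale and back-transformed (by plain
#' exponentiation) so that the stored criteria are always on the original
#' biomass scale and comparable across transforms.  The log-scale criteria
#' are kept alongside.
#'
#' Predictors are used in their measurement units by default, as is usual in
#' this estimation tradition; `standardize = TRUE` optionally z-scores each
#' predictor (training mean/sd) before distance computation.
#'
#' @param data A [tree_data] object on the raw scale.
#' @param variables Predictor subset used for distances; see
#'   [predictor_sets()] for the canonical choices.  Default: all six.
#' @param k Number of neighbours, `1 <= k <= n - 1`.  The canonical sweep
#'   values are 1, 3, 5, 7, 9, 11; other values are accepted with a warning.
#' @param metric Distance metric, see [tree_distance()].
#' @param weighting Neighbour weighting, `"inv_d"` or `"inv_d2"`.
#' @param use_log Log-transform predictors and response before estimation?
#' @param standardize Z-score predictors before distance computation?
#' @param literal_manhattan Audit switch, see [tree_distance()].
#' @return An object of class `"knn_biomass"` with components `config`,
#'   `loocv` (actual and predicted biomass on the working scale), `criteria`
#'   (a [fit_criteria()] set on the original scale), and
#'   `criteria_transformed` (log-scale criteria, when `use_log`).  Methods:
#'   `print`, `summary`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' ds <- simulate_trees(n = 60, seed = 42)
#' fit <- knn_biomass(ds, k = 5, metric = "chebyshev")
#' fit
#' summary(fit)$criteria$syx
#' @export
knn_biomass <- function(data, variables = tree_variables, k = 5,
                        metric = c("euclidean", "quadratic_euclidean",
                                   "manhattan", "chebyshev"),
                        weighting = c("inv_d", "inv_d2"),
                        use_log = FALSE, standardize = FALSE,
                        literal_manhattan = FALSE) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "tree_data"))
  if (attr(data, "transform") != "raw")
    stop("'data' must be on the raw scale; use_log = TRUE handles the ",
         "transformation internally", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1)
    stop("'k' must be a single positive whole number", call. = FALSE)
  k <- as.integer(k)
  n <- nrow(data)
  if (k > n - 1L)
    stop("'k' (", k, ") must be at most n - 1 = ", n - 1L,
         " under leave-one-out cross-validation", call. = FALSE)
  if (!k %in% .canonical_k)
    warning("k = ", k, " is outside the canonical neighbour grid {",
            paste(.canonical_k, collapse = ", "), "}", call. = FALSE)

  work <- if (use_log) log_transform(data) else data
  feat <- tree_features(work, variables)
  x <- feat$x
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, stats::sd)
    if (any(scale_ == 0))
      stop("cannot standardize: constant predictor '",
           colnames(x)[which(scale_ == 0)[1L]], "'", call. = FALSE)
    x <- scale(x, center = center, scale = scale_)
    attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  }

  D <- .distance_matrix(x, metric, literal_manhattan)
  pred <- .loocv_from_dist(D, feat$y, k, weighting)

  w_actual <- data$w
  w_pred <- if (use_log) exp(pred) else pred
  ## criteria need n >= n_params + 2; tiny fits stay usable for prediction
  crit <- crit_log <- NULL
  if (n >= length(variables) + 2L) {
    crit <- fit_criteria(w_actual, w_pred, n_params = length(variables))
    if (use_log)
      crit_log <- fit_criteria(feat$y, pred, n_params = length(variables))
  }

  structure(list(
    call = match.call(),
    config = list(metric = metric, k = k, weighting = weighting,
                  variables = variables, use_log = use_log,
                  standardize = standardize,
                  literal_manhattan = literal_manhattan),
    n = n,
    train = list(x = x, y = feat$y, w = w_actual,
                 record_id = data$record_id,
                 center = center, scale = scale_),
    loocv = list(actual = w_actual, predicted = w_pred,
                 actual_transformed = if (use_log) feat$y,
                 predicted_transformed = if (use_log) pred,
                 scale = if (use_log) "log" else "original"),
    criteria = crit,
    criteria_transformed = crit_log
  ), class = "knn_biomass")
}

#' Neighbours of a training record
#'
#' Returns the `k` nearest neighbours of one training record under the fit's
#' configuration, excluding the record itself (the leave-one-out view used
#' during cross-validation).  Ties at the neighbourhood boundary are broken
#' by ascending record position.
#'
#' @param object A fitted `knn_biomass` model.
#' @param query Index of the query record in the training data.
#' @return Data frame with columns `index`, `record_id`, `distance`
#'   (ascending) and `w` (neighbour biomass on the working scale).
#' @export
nearest_neighbors <- function(object, query) {
  stopifnot(inherits(object, "knn_biomass"))
  n <- object$n
  if (!is.numeric(query) || length(query) != 1L || query < 1 || query > n ||
      query != round(query))
    stop("'query' must be a record index in 1..", n, call. = FALSE)
  cfg <- object$config
  d <- .cross_distances(object$train$x[query, , drop = FALSE],
                        object$train$x, cfg$metric,
                        cfg$literal_manhattan)[1L, ]
  d[query] <- Inf
  nb <- order(d)[seq_len(cfg$k)]
  data.frame(index = nb, record_id = object$train$record_id[nb],
             distance = d[nb], w = object$train$y[nb])
}

#' Predict biomass for new trees
#'
#' @param object A fitted `knn_biomass` model.
#' @param newdata Data frame with the fit's predictor columns; omit to
#'   return the leave-one-out predictions for the training records.
#' @param scale `"original"` returns biomass in measurement units
#'   (back-transforming when the fit is on the log scale); `"transformed"`
#'   returns the working-scale prediction.
#' @param ... Unused.
#' @return Numeric vector of predicted biomass.
#' @export
predict.knn_biomass <- function(object, newdata = NULL,
                                scale = c("original", "transformed"), ...) {
  scale <- match.arg(scale)
  if (is.null(newdata)) {
    return(if (scale == "original") object$loocv$predicted
           else if (object$config$use_log) object$loocv$predicted_transformed
           else object$loocv$predicted)
  }
  cfg <- object$config
  miss <- setdiff(cfg$variables, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(as.data.frame(newdata)[cfg$variables])
  if (!all(is.finite(x))) stop("non-finite predictor value", call. = FALSE)
  if (cfg$use_log) {
    if (any(x <= 0))
      stop("log-scale fit requires strictly positive predictors",
           call. = FALSE)
    x <- log(x)
  }
  if (cfg$standardize)
    x <- sweep(sweep(x, 2L, object$train$center), 2L, object$train$scale, "/")
  D <- .cross_distances(x, object$train$x, cfg$metric, cfg$literal_manhattan)
  pred <- vapply(seq_len(nrow(x)), function(i) {
    nb <- order(D[i, ])[seq_len(cfg$k)]
    weighted_estimate(object$train$y[nb], D[i, nb], cfg$weighting)
  }, numeric(1))
  if (cfg$use_log && scale == "original") exp(pred) else pred
}

#' @export
fitted.knn_biomass <- function(object, ...) object$loocv$predicted

#' Leave-one-out residuals of a nearest-neighbour biomass fit
#'
#' @param object A fitted `knn_biomass` model.
#' @param scale Residual scale; `"original"` is actual minus predicted
#'   biomass in measurement units.
#' @param ... Unused.
#' @export
residuals.knn_biomass <- function(object,
                                  scale = c("original", "transformed"), ...) {
  scale <- match.arg(scale)
  if (scale == "transformed" && object$config$use_log)
    object$loocv$actual_transformed - object$loocv$predicted_transformed
  else object$loocv$actual - object$loocv$predicted
}

#' @export
print.knn_biomass <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Nearest-neighbour biomass estimator\n")
  cat(sprintf("  %d records, k = %d, %s distance, %s weighting\n",
              x$n, cfg$k, cfg$metric, cfg$weighting))
  cat(sprintf("  predictors: %s%s%s\n",
              paste(cfg$variables, collapse = ", "),
              if (cfg$use_log) " (log scale)" else "",
              if (cfg$standardize) " (standardized)" else ""))
  if (!is.null(x$criteria))
    cat(sprintf("  LOOCV (original scale): Syx = %s, R2adj = %s\n",
                format(x$criteria$syx, digits = digits),
                format(x$criteria$r2_adj, digits = digits)))
  invisible(x)
}

#' @export
summary.knn_biomass <- function(object, ...) {
  res <- residuals(object)
  out <- list(config = object$config, n = object$n,
              criteria = object$criteria,
              criteria_transformed = object$criteria_transformed,
              residual_summary = summary(res))
  class(out) <- "summary.knn_biomass"
  out
}

#' @export
print.summary.knn_biomass <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Nearest-neighbour biomass estimator (leave-one-out assessment)\n\n")
  cat(sprintf("n = %d, k = %d, metric = %s, weighting = %s\n", x$n, cfg$k,
              cfg$metric, cfg$weighting))
  cat("predictors:", paste(cfg$variables, collapse = ", "),
      if (cfg$use_log) "(log scale)" else "", "\n\n")
  cat("Criteria (original biomass scale):\n")
  print(x$criteria, digits = digits)
  if (!is.null(x$criteria_transformed)) {
    cat("\nCriteria (log scale):\n")
    print(x$criteria_transformed, digits = digits)
  }
  cat("\nLOOCV residuals (original scale):\n")
  print(x$residual_summary, digits = digits)
  invisible(x)
}

#' Residual plot of a nearest-neighbour biomass fit
#'
#' Two panels: observed versus leave-one-out predicted biomass with the 1:1
#' line, and residuals against predicted values.
#'
#' @param x A fitted `knn_biomass` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.knn_biomass <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  a <- x$loocv$actual; p <- x$loocv$predicted
  graphics::plot(p, a, xlab = "Predicted biomass (LOOCV)",
                 ylab = "Observed biomass", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(p, a - p, xlab = "Predicted biomass (LOOCV)",
                 ylab = "Residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
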