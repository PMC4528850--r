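#' Define a configuration grid for the estimation benchmark
#'
#' A grid is the full crossing of five experimental arms: distance metric,
#' neighbour weighting, neighbour count, predictor subset and scale
#' transform, optionally crossed with a data-size-reduction arm.  Defaults
#' are the canonical sweep: all four metrics, both weightings,
#' k in \{1, 3, 5, 7, 9, 11\}, the four predictor subsets of
#' [predictor_sets()], raw and log scales, and the full dataset plus
#' randomly reduced series of 150, 100, 70 and 50 trees.
#'
#' @param metrics Character vector of distance metrics.
#' @param weightings Character vector, subset of `c("inv_d", "inv_d2")`.
#' @param k Integer vector of neighbour counts.
#' @param variable_sets Named list of predictor subsets.
#' @param transforms Subset of `c("raw", "log")`.
#' @param sizes Data-size arm: `NULL` for the full dataset only, otherwise a
#'   vector of target sizes where `NA` stands for the full dataset.  Each
#'   reduced series is drawn once per run seed, so all cells sharing a size
#'   see the same records.
#' @param seed Integer seed fixing the reduced series (and hence the whole
#'   run).
#' @return Object of class `"experiment_grid"`.
#' @examples
#' experiment_grid(sizes = NULL)  # the 192-cell single-dataset grid
#' @export
experiment_grid <- function(metrics = .knn_metrics,
                            weightings = c("inv_d", "inv_d2"),
                            k = c(1, 3, 5, 7, 9, 11),
                            variable_sets = predictor_sets(),
                            transforms = c("raw", "log"),
                            sizes = c(NA, 150, 100, 70, 50),
                            seed = 1L) {
  metrics <- match.arg(metrics, .knn_metrics, several.ok = TRUE)
  weightings <- match.arg(weightings, c("inv_d", "inv_d2"),
                          several.ok = TRUE)
  transforms <- match.arg(transforms, c("raw", "log"), several.ok = TRUE)
  if (!is.list(variable_sets) || !length(variable_sets))
    stop("'variable_sets' must be a non-empty list", call. = FALSE)
  if (is.null(names(variable_sets)))
    names(variable_sets) <- vapply(variable_sets, paste, "", collapse = "+")
  if (any(!vapply(k, function(z) z == round(z) && z >= 1, logical(1))))
    stop("'k' values must be positive whole numbers", call. = FALSE)
  structure(list(metrics = metrics, weightings = weightings,
                 k = as.integer(k), variable_sets = variable_sets,
                 transforms = transforms, sizes = sizes,
                 seed = as.integer(seed)),
            class = "experiment_grid")
}

.grid_cells <- function(grid) {
  n_sizes <- if (is.null(grid$sizes)) 1L else length(grid$sizes)
  n_sizes * length(grid$transforms) * length(grid$variable_sets) *
    length(grid$metrics) * length(grid$weightings) * length(grid$k)
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("Estimation benchmark grid:", .grid_cells(x), "cells\n")
  cat("  metrics:   ", paste(x$metrics, collapse = ", "), "\n")
  cat("  weightings:", paste(x$weightings, collapse = ", "), "\n")
  cat("  k:         ", paste(x$k, collapse = ", "), "\n")
  cat("  subsets:   ", paste(names(x$variable_sets), collapse = ", "), "\n")
  cat("  transforms:", paste(x$transforms, collapse = ", "), "\n")
  cat("  sizes:     ",
      if (is.null(x$sizes)) "full dataset only"
      else paste(ifelse(is.na(x$sizes), "full", x$sizes), collapse = ", "),
      "\n")
  cat("  seed:      ", x$seed, "\n")
  invisible(x)
}

#' Run a configuration grid
#'
#' Evaluates every cell of the grid on the dataset: seeded subsampling for
#' the data-size arm, optional log transform, leave-one-out
#' nearest-neighbour prediction, and model-selection criteria on the
#' original biomass scale (log-scale predictions are back-transformed before
#' the criteria, so all cells are comparable).  Infeasible cells — a
#' neighbour count of at least the cell's sample size, a requested size
#' exceeding the dataset, or a transform failure — are marked `failed` with
#' a reason and never abort the run.  Rows appear in fixed enumeration order
#' (size, transform, subset, metric, weighting, k, innermost last), and a
#' rerun with the same seed is identical.
#'
#' @param data A [tree_data] object on the raw scale.
#' @param grid An [experiment_grid()].
#' @return Data frame of class `"grid_results"`, one row per cell:
#'   configuration descriptor columns, `status`/`reason`, and the criteria
#'   `r2, r2_adj, syx, aic, aicc, bic` (original scale, `NA` for failed
#'   cells).
#' @examples
#' ds <- simulate_trees(n = 60, seed = 5)
#' res <- run_grid(ds, experiment_grid(k = c(1, 5), sizes = NULL))
#' summary(res)
#' @export
run_grid <- function(data, grid = experiment_grid()) {
  stopifnot(inherits(data, "tree_data"), inherits(grid, "experiment_grid"))
  if (attr(data, "transform") != "raw")
    stop("'data' must be on the raw scale", call. = FALSE)
  n_full <- nrow(data)

  ## data-size arm: all reduced series drawn from one seeded stream, once
  sizes <- grid$sizes
  if (is.null(sizes)) sizes <- NA
  datasets <- with_seed(grid$seed, lapply(sizes, function(s) {
    if (is.na(s)) return(list(label = "full", data = data))
    if (s > n_full)
      return(list(label = as.character(s), data = NULL,
                  reason = paste0("requested size ", s, " exceeds n = ",
                                  n_full)))
    list(label = as.character(s), data = subsample_trees(data, s))
  }))

  rows <- vector("list", .grid_cells(grid))
  r <- 0L
  for (ds_arm in datasets) {
    for (tr in grid$transforms) {
      ds_tr <- NULL; tr_reason <- ds_arm$reason
      if (is.null(tr_reason)) {
        ds_tr <- if (tr == "log")
          tryCatch(log_transform(ds_arm$data), error = function(e) {
            tr_reason <<- conditionMessage(e); NULL
          })
        else ds_arm$data
      }
      for (vs_name in names(grid$variable_sets)) {
        vars <- grid$variable_sets[[vs_name]]
        base_row <- data.frame(
          size = ds_arm$label,
          n = if (is.null(ds_tr)) NA_integer_ else nrow(ds_tr),
          transform = tr, subset = vs_name,
          variables = paste(vars, collapse = "+"),
          stringsAsFactors = FALSE)
        for (met in grid$metrics) {
          D <- y <- w_orig <- NULL
          if (!is.null(ds_tr)) {
            feat <- tree_features(ds_tr, vars)
            D <- .distance_matrix(feat$x, met)
            y <- feat$y
            w_orig <- ds_arm$data$w
          }
          for (wt in grid$weightings) {
            for (kk in grid$k) {
              r <- r + 1L
              row <- cbind(base_row,
                           data.frame(metric = met, weighting = wt, k = kk,
                                      stringsAsFactors = FALSE))
              if (!is.null(tr_reason)) {
                row$status <- "failed"; row$reason <- tr_reason
                row[c("r2", "r2_adj", "syx", "aic", "aicc", "bic")] <- NA_real_
              } else if (kk >= length(y)) {
                row$status <- "failed"
                row$reason <- paste0("k = ", kk, " >= n = ", length(y))
                row[c("r2", "r2_adj", "syx", "aic", "aicc", "bic")] <- NA_real_
              } else {
                pred <- .loocv_from_dist(D, y, kk, wt)
                if (tr == "log") pred <- exp(pred)
                crit <- fit_criteria(w_orig, pred, n_params = length(vars))
                row$status <- "ok"; row$reason <- ""
                row$r2 <- crit$r2; row$r2_adj <- crit$r2_adj
                row$syx <- crit$syx; row$aic <- crit$aic
                row$aicc <- crit$aicc; row$bic <- crit$bic
              }
              rows[[r]] <- row
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  class(out) <- c("grid_results", "data.frame")
  out
}

#' @export
summary.grid_results <- function(object, top = 5L, ...) {
  ok <- object[object$status == "ok", , drop = FALSE]
  out <- list(cells = nrow(object), ok = nrow(ok),
              failed = sum(object$status == "failed"),
              top = utils::head(ok[order(ok$syx), ], top))
  class(out) <- "summary.grid_results"
  out
}

#' @export
print.summary.grid_results <- function(x, ...) {
  cat(sprintf("Grid run: %d cells (%d ok, %d failed)\n", x$cells, x$ok,
              x$failed))
  cat("Best configurations by Syx (original scale):\n")
  print.data.frame(
    x$top[c("size", "transform", "subset", "metric", "weighting", "k",
            "syx", "r2_adj", "aic")],
    digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.grid_results <- function(x, ...) {
  print(summary(x))
  cat("(", nrow(x), "rows; use as.data.frame() for the full table )\n")
  invisible(x)
}

#' Write grid results to CSV
#'
#' One row per configuration with all criteria; the standard export format
#' for downstream plotting.
#'
#' @param results A `grid_results` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_results <- function(results, path) {
  stopifnot(inherits(results, "grid_results"))
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Compare nearest-neighbour estimation to Schumacher-Hall allometry
#'
#' Fits the Schumacher-Hall model to the dataset and evaluates a
#' nearest-neighbour configuration under every distance metric, all judged
#' out-of-sample on the original biomass scale: the kNN side by leave-one-out
#' cross-validation, the regression side by exact leave-one-out OLS
#' predictions (back-transformed).  The headline statistic is the percent
#' Syx gain of each metric over the regression reference ([syx_gain()]);
#' in-sample fitted-regression criteria are reported alongside.
#'
#' @param data A [tree_data] object on the raw scale.
#' @param variables Predictor subset for the kNN side (default all six).
#' @param k Neighbour count.
#' @param weighting Neighbour weighting.
#' @param metrics Distance metrics to evaluate.
#' @param use_log Run the kNN side on the log scale?
#' @return Object of class `"biomass_comparison"`: the `schumacher_hall`
#'   fit, its LOO and fitted criteria, per-metric `knn_biomass` fits and
#'   criteria, and the named `gains` vector (percent).  Methods: `print`,
#'   `plot`.
#' @examples
#' ds <- simulate_mixed_forest(n = 120, seed = 11)
#' cmp <- compare_to_allometry(ds)
#' cmp$gains
#' @export
compare_to_allometry <- function(data, variables = tree_variables, k = 5,
                                 weighting = "inv_d",
                                 metrics = .knn_metrics, use_log = FALSE) {
  stopifnot(inherits(data, "tree_data"))
  sh <- schumacher_hall(data)
  sh_loo <- predict(sh, loo = TRUE)            # original scale, out-of-sample
  sh_crit_loo <- fit_criteria(data$w, sh_loo, n_params = 3L)
  sh_crit_fit <- fit_criteria(data$w, fitted(sh), n_params = 3L)

  fits <- lapply(metrics, function(m)
    knn_biomass(data, variables = variables, k = k, metric = m,
                weighting = weighting, use_log = use_log))
  names(fits) <- metrics
  knn_crit <- lapply(fits, `[[`, "criteria")
  gains <- vapply(knn_crit, function(cr) syx_gain(sh_crit_loo, cr),
                  numeric(1))
  best <- metrics[which.min(vapply(knn_crit, `[[`, numeric(1), "syx"))]

  structure(list(sh = sh, sh_criteria_loo = sh_crit_loo,
                 sh_criteria_fit = sh_crit_fit,
                 knn = fits, knn_criteria = knn_crit, gains = gains,
                 best_metric = best, k = k, weighting = weighting,
                 variables = variables, use_log = use_log),
            class = "biomass_comparison")
}

#' @export
print.biomass_comparison <- function(x, digits = 4, ...) {
  cat("Nearest-neighbour estimation vs Schumacher-Hall allometry\n")
  cat(sprintf("  kNN: k = %d, %s weighting, predictors %s\n", x$k,
              x$weighting, paste(x$variables, collapse = ", ")))
  cat(sprintf("  Schumacher-Hall LOO Syx = %s (fitted Syx = %s), n = %d\n\n",
              format(x$sh_criteria_loo$syx, digits = digits),
              format(x$sh_criteria_fit$syx, digits = digits), x$sh$n))
  tab <- data.frame(
    metric = names(x$knn_criteria),
    syx = vapply(x$knn_criteria, `[[`, numeric(1), "syx"),
    r2_adj = vapply(x$knn_criteria, `[[`, numeric(1), "r2_adj"),
    gain_pct = x$gains, row.names = NULL)
  print.data.frame(tab, digits = digits, row.names = FALSE)
  cat("\nBest metric by Syx:", x$best_metric, "\n")
  invisible(x)
}

#' Residual comparison plot
#'
#' Side-by-side residual scatter (residual against predicted biomass) for
#' the best nearest-neighbour configuration and the Schumacher-Hall model,
#' both out-of-sample.
#'
#' @param x A `biomass_comparison` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.biomass_comparison <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  bf <- x$knn[[x$best_metric]]
  p1 <- bf$loocv$predicted; r1 <- bf$loocv$actual - p1
  sh_loo <- predict(x$sh, loo = TRUE)
  r2 <- x$sh$data$w - sh_loo
  ylim <- range(r1, r2)
  graphics::plot(p1, r1, ylim = ylim, xlab = "Predicted biomass",
                 ylab = "Residual", main = paste0("kNN (", x$best_metric, ")"),
                 ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(sh_loo, r2, ylim = ylim, xlab = "Predicted biomass",
                 ylab = "Residual", main = "Schumacher-Hall", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Accuracy as a function of the neighbour count
#'
#' Evaluates one nearest-neighbour configuration over a vector of `k`
#' values, all other settings fixed, returning the model-selection criteria
#' per `k` (original biomass scale).  Used to locate the optimal
#' neighbourhood size: too few neighbours are noise-sensitive, too many
#' oversmooth.
#'
#' @param data A [tree_data] object on the raw scale.
#' @param k_values Neighbour counts to sweep, all below `nrow(data)`.
#' @param variables,metric,weighting,use_log As in [knn_biomass()].
#' @return Data frame of class `"neighbor_sweep"` with columns `k, r2,
#'   r2_adj, syx, aic, aicc, bic`.  A `plot` method draws Syx against k.
#' @examples
#' ds <- simulate_mixed_forest(n = 100, seed = 2)
#' sw <- neighbor_sweep(ds)
#' sw$k[which.min(sw$syx)]
#' @export
neighbor_sweep <- function(data, k_values = c(1, 3, 5, 7, 9, 11),
                           variables = tree_variables,
                           metric = "chebyshev", weighting = "inv_d",
                           use_log = FALSE) {
  stopifnot(inherits(data, "tree_data"))
  metric <- match.arg(metric, .knn_metrics)
  if (any(k_values != round(k_values)) || any(k_values < 1))
    stop("'k_values' must be positive whole numbers", call. = FALSE)
  if (max(k_values) >= nrow(data))
    stop("max(k_values) must be below the number of records", call. = FALSE)
  work <- if (use_log) log_transform(data) else data
  feat <- tree_features(work, variables)
  D <- .distance_matrix(feat$x, metric)
  rows <- lapply(as.integer(k_values), function(kk) {
    pred <- .loocv_from_dist(D, feat$y, kk, weighting)
    if (use_log) pred <- exp(pred)
    cbind(data.frame(k = kk),
          as.data.frame(fit_criteria(data$w, pred,
                                     n_params = length(variables)))[
            c("r2", "r2_adj", "syx", "aic", "aicc", "bic")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(variables = variables, metric = metric,
                              weighting = weighting, use_log = use_log)
  class(out) <- c("neighbor_sweep", "data.frame")
  out
}

#' @export
plot.neighbor_sweep <- function(x, ...) {
  cfg <- attr(x, "config")
  graphics::plot(x$k, x$syx, type = "b", xlab = "Neighbours (k)",
                 ylab = "Syx",
                 main = paste0(cfg$metric, ", ", cfg$weighting), ...)
  invisible(x)
}
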