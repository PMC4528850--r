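#' Distance between two feature vectors
#'
#' The four metrics used to define nearest neighbours in feature space:
#' Euclidean \eqn{\sqrt{\sum \Delta^2}}, quadratic Euclidean
#' \eqn{\sum \Delta^2}, Manhattan \eqn{\sum |\Delta|} and Chebyshev
#' \eqn{\max |\Delta|}, where \eqn{\Delta} is the coordinate-wise
#' difference on the selected predictor variables.
#'
#' `literal_manhattan = TRUE` replaces the Manhattan metric by the sum of
#' squared absolute differences.  That form circulates in some of the
#' applied literature under the Manhattan name but is identical to the
#' quadratic Euclidean distance; it is provided only for auditing results
#' computed under that convention, and the standard city-block definition is
#' the default.
#'
#' @param p,q Numeric vectors of equal length, all values finite.
#' @param metric One of `"euclidean"`, `"quadratic_euclidean"`,
#'   `"manhattan"`, `"chebyshev"`.
#' @param literal_manhattan Audit switch, see Details.
#' @return A single non-negative number.  For every metric the distance is
#'   symmetric and zero exactly when `p == q`.
#' @examples
#' tree_distance(c(1, 5, 2), c(2, 1, 2), "chebyshev")  # 4
#' tree_distance(c(1, 5, 2), c(2, 1, 2), "manhattan")  # 5
#' @export
tree_distance <- function(p, q,
                          metric = c("euclidean", "quadratic_euclidean",
                                     "manhattan", "chebyshev"),
                          literal_manhattan = FALSE) {
  metric <- match.arg(metric)
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length", call. = FALSE)
  if (!length(p)) stop("vectors must have length >= 1", call. = FALSE)
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("non-finite value in input vectors", call. = FALSE)
  d <- abs(p - q)
  switch(metric,
         euclidean           = sqrt(sum(d^2)),
         quadratic_euclidean = sum(d^2),
         manhattan           = if (literal_manhattan) sum(d^2) else sum(d),
         chebyshev           = max(d))
}

.knn_metrics <- c("euclidean", "quadratic_euclidean", "manhattan",
                  "chebyshev")

## Full pairwise distance matrix on a feature matrix; stats::dist does the
## heavy lifting (method "maximum" is Chebyshev).
.distance_matrix <- function(x, metric, literal_manhattan = FALSE) {
  metric <- match.arg(metric, .knn_metrics)
  if (metric == "manhattan" && literal_manhattan)
    metric <- "quadratic_euclidean"
  switch(metric,
         euclidean           = as.matrix(stats::dist(x, method = "euclidean")),
         quadratic_euclidean = as.matrix(stats::dist(x, method = "euclidean"))^2,
         manhattan           = as.matrix(stats::dist(x, method = "manhattan")),
         chebyshev           = as.matrix(stats::dist(x, method = "maximum")))
}

## Distances from each row of `x` (queries) to each row of `ref`.
## Returns a nrow(x) x nrow(ref) matrix.
.cross_distances <- function(x, ref, metric, literal_manhattan = FALSE) {
  out <- matrix(0, nrow(x), nrow(ref))
  for (i in seq_len(nrow(x)))
    for (j in seq_len(nrow(ref)))
      out[i, j] <- tree_distance(x[i, ], ref[j, ], metric,
                                 literal_manhattan = literal_manhattan)
  out
}
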