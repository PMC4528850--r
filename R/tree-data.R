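#' Per-tree measurement variables
#'
#' The six predictor variables carried by a tree dataset, in canonical order:
#' `dbh` (diameter at breast height, cm), `dm` (mean crown diameter, m),
#' `ht` (total height, m), `hc` (height of the lowest living branch, m),
#' `da` (apparent wood density, g/cm^3) and `db` (basic wood density,
#' g/cm^3).  The response is `w`, total dry biomass (kg).
#'
#' @format Character vector of length 6.
#' @export
tree_variables <- c("dbh", "dm", "ht", "hc", "da", "db")

.required_columns <- c(tree_variables, "w")

#' Canonical predictor subsets
#'
#' The four nested predictor sets commonly swept when benchmarking
#' nearest-neighbour biomass estimation: diameter only; diameter and height;
#' diameter, height and both wood densities; and all six variables.
#'
#' @return Named list of character vectors, each a subset of
#'   [tree_variables] in canonical order.
#' @examples
#' predictor_sets()
#' @export
predictor_sets <- function() {
  list(
    dbh            = "dbh",
    dbh_ht         = c("dbh", "ht"),
    dbh_ht_density = c("dbh", "ht", "da", "db"),
    all            = tree_variables
  )
}

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.  seed = NULL runs expr on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct and validate a tree dataset
#'
#' Checks a data frame of per-tree records against the structural rules a
#' biomass dataset must satisfy and returns it classed as `"tree_data"`.
#' Required columns are the six predictors in [tree_variables] plus the
#' response `w`; a `record_id` column is added (row sequence) when absent and
#' an optional `species` label column is carried through untouched.
#'
#' Validation on the raw scale requires every predictor and `w` to be
#' strictly positive, except `hc` which may be zero (a living branch at
#' ground level); additionally `hc <= ht` and `db <= da` (basic density never
#' exceeds apparent density).  On the log scale (see [log_transform()]) the
#' positivity checks do not apply but the two order constraints, which are
#' preserved by the logarithm, still do.
#'
#' @param df Data frame with at least the columns
#'   `dbh, dm, ht, hc, da, db, w`.
#' @param transform Scale flag, `"raw"` (measurement units) or `"log"`
#'   (natural logarithms of all variables).
#' @param provenance Optional free-text note on where the data came from.
#' @return A data frame of class `c("tree_data", "data.frame")` with
#'   attributes `transform` and `provenance`.
#' @seealso [read_tree_data()], [log_transform()], [simulate_trees()]
#' @examples
#' df <- data.frame(dbh = c(5, 10), dm = c(1, 2), ht = c(4, 8),
#'                  hc = c(1, 2), da = c(0.7, 0.75), db = c(0.5, 0.6),
#'                  w = c(6, 40))
#' tree_data(df)
#' @export
tree_data <- function(df, transform = c("raw", "log"), provenance = NULL) {
  transform <- match.arg(transform)
  if (!is.data.frame(df)) stop("'df' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) < 2L)
    stop("a tree dataset needs at least 2 records", call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$record_id)) df$record_id <- seq_len(nrow(df))
  if (anyDuplicated(df$record_id))
    stop("'record_id' values must be unique", call. = FALSE)

  for (v in .required_columns) {
    x <- df[[v]]
    if (!is.numeric(x))
      stop("column '", v, "' must be numeric", call. = FALSE)
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-finite value in '", v, "' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (transform == "raw") {
    for (v in setdiff(.required_columns, "hc")) {
      bad <- which(df[[v]] <= 0)
      if (length(bad))
        stop("non-positive value in '", v, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- which(df$hc < 0)
    if (length(bad))
      stop("negative value in 'hc' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$hc > df$ht)
  if (length(bad))
    stop("'hc' exceeds 'ht' at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(df$db > df$da)
  if (length(bad))
    stop("'db' exceeds 'da' at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)

  keep <- c("record_id", .required_columns,
            if ("species" %in% names(df)) "species")
  out <- df[keep]
  attr(out, "transform") <- transform
  attr(out, "provenance") <- provenance
  class(out) <- c("tree_data", "data.frame")
  out
}

#' @export
print.tree_data <- function(x, ...) {
  cat(sprintf("Tree dataset: %d records (%s scale)\n", nrow(x),
              attr(x, "transform")))
  if (!is.null(attr(x, "provenance")))
    cat("Provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a tree dataset from CSV
#'
#' Reads a comma-separated file (header row, `.` decimal mark, UTF-8) with
#' one tree per row and at least the columns `dbh, dm, ht, hc, da, db, w`,
#' and validates it with [tree_data()].  File order is preserved.
#'
#' @param path Path to a CSV file.
#' @param transform Scale the file is on; almost always `"raw"`.
#' @return A `tree_data` object.
#' @seealso [write_tree_data()]
#' @export
read_tree_data <- function(path, transform = "raw") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  tree_data(df, transform = transform, provenance = path)
}

#' Write a tree dataset to CSV
#'
#' Writes the dataset in the same dialect [read_tree_data()] expects.
#' Numeric values are written with 17 significant digits so that a
#' write-then-read round trip reproduces every double exactly.
#'
#' @param data A `tree_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_data <- function(data, path) {
  stopifnot(inherits(data, "tree_data"))
  out <- as.data.frame(data)
  for (v in names(out))
    if (is.double(out[[v]])) out[[v]] <- sprintf("%.17g", out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Natural-log transform of a tree dataset
#'
#' Replaces every predictor and the biomass response by its natural
#' logarithm, returning a new dataset flagged as log scale; the input is not
#' modified.  All values must be strictly positive: an `hc` of zero is an
#' error rather than being silently offset, since an undocumented constant
#' would change distances invisibly.
#'
#' @param data A `tree_data` object on the raw scale.
#' @return A `tree_data` object with `transform = "log"`.
#' @examples
#' ds <- simulate_trees(n = 10, seed = 1)
#' lds <- log_transform(ds)
#' all.equal(exp(lds$w), ds$w)
#' @export
log_transform <- function(data) {
  stopifnot(inherits(data, "tree_data"))
  if (attr(data, "transform") != "raw")
    stop("dataset is already log-transformed", call. = FALSE)
  out <- as.data.frame(data)
  for (v in .required_columns) {
    bad <- which(out[[v]] <= 0)
    if (length(bad))
      stop("cannot log-transform '", v, "': non-positive value at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    out[[v]] <- log(out[[v]])
  }
  tree_data(out, transform = "log", provenance = attr(data, "provenance"))
}

#' Seeded random subsample of a tree dataset
#'
#' Draws a simple random sample of records without replacement, preserving
#' the relative record order of the parent dataset.  The same seed always
#' yields the same sample, which is how reduced data series (e.g. 150, 100,
#' 70, 50 trees out of 180) are fixed for an experiment run.
#'
#' @param data A `tree_data` object.
#' @param n Target number of records, `2 <= n <= nrow(data)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `tree_data` object with `n` records.
#' @export
subsample_trees <- function(data, n, seed = NULL) {
  stopifnot(inherits(data, "tree_data"))
  n_full <- nrow(data)
  if (!is.numeric(n) || length(n) != 1L || n != round(n))
    stop("'n' must be a single whole number", call. = FALSE)
  if (n > n_full)
    stop("requested ", n, " records but the dataset has only ", n_full,
         call. = FALSE)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  idx <- if (n == n_full) seq_len(n_full) else
    sort(with_seed(seed, sample.int(n_full, n)))
  out <- data[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "transform") <- attr(data, "transform")
  attr(out, "provenance") <- attr(data, "provenance")
  class(out) <- c("tree_data", "data.frame")
  out
}

#' Extract a feature matrix and biomass response
#'
#' Projects a dataset onto an ordered subset of the predictor variables,
#' returning the design matrix used for distance computation together with
#' the biomass response, both in record order.
#'
#' @param data A `tree_data` object.
#' @param variables Character vector of predictor names, a subset of
#'   [tree_variables].
#' @return List with components `x` (numeric matrix, n x length(variables),
#'   columns in the requested order) and `y` (numeric response vector).
#' @export
tree_features <- function(data, variables = tree_variables) {
  stopifnot(inherits(data, "tree_data"))
  unknown <- setdiff(variables, tree_variables)
  if (length(unknown))
    stop("unknown predictor variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(variables)) stop("'variables' must be non-empty", call. = FALSE)
  if (anyDuplicated(variables))
    stop("duplicated predictor variable(s)", call. = FALSE)
  x <- as.matrix(as.data.frame(data)[variables])
  rownames(x) <- NULL
  list(x = x, y = data$w)
}
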