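# Independent brute-force oracles, deliberately coded from the distance and
# weighting definitions rather than through the package's computational path.

oracle_dist <- function(p, q, metric) {
  d <- abs(p - q)
  switch(metric,
         euclidean = sqrt(sum(d * d)),
         quadratic_euclidean = sum(d * d),
         manhattan = sum(d),
         chebyshev = max(d))
}

oracle_loocv <- function(x, y, k, metric, weighting) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) oracle_dist(x[i, ], x[j, ], metric),
                numeric(1))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    dd <- d[nb]
    if (any(dd == 0)) return(mean(y[nb][dd == 0]))
    u <- if (weighting == "inv_d") 1 / dd else 1 / dd^2
    sum(u * y[nb]) / sum(u)
  }, numeric(1))
}

# Small deterministic dataset satisfying all record constraints, no RNG.
toy_trees <- function(n = 6) {
  dbh <- seq(4, 18, length.out = n)
  ht <- 2 + 0.55 * dbh
  tree_data(data.frame(
    dbh = dbh,
    dm = 0.3 + 0.12 * dbh,
    ht = ht,
    hc = 0.25 * ht,
    da = 0.6 + 0.005 * dbh,
    db = 0.45 + 0.004 * dbh,
    w = 0.1 * dbh^2
  ))
}
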