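#' Simulate a synthetic allometric tree dataset
#'
#' Generates per-tree records with the statistical structure of a young
#' mixed-species restoration planting: a right-skewed diameter
#' distribution, height and crown dimensions that grow allometrically with
#' diameter, wood densities positively correlated with size, and total dry
#' biomass following the log-linear law
#' \deqn{w = \exp(a + b \ln(dbh) + c \ln(ht) + \epsilon), \quad
#'       \epsilon \sim N(0, \sigma^2)}
#' (multiplicative lognormal error).  The default coefficients are those of
#' a published Schumacher-Hall fit for Atlantic Forest restoration
#' plantings, so the simulated biomass magnitudes are realistic for trees of
#' 1-25 cm diameter.
#'
#' With `n_species > 1` the generator emulates between-species heterogeneity
#' in the allometry, structured as a deterministic gradient of ecological
#' strategies from fast-growing pioneers to slow-growing, dense-wooded
#' species — the classic functional contrast of restoration plantings.
#' Species labels are assigned to trees uniformly at random; species `j`
#' sits at position \eqn{t_j} on a centred contrast ladder with unit
#' standard deviation (for two species, \eqn{t = \mp 1/\sqrt 2}) and
#' receives:
#' \itemize{
#'   \item a wood-density multiplier \eqn{\exp(-t_j d)} with
#'     `d = density_spread`, applied to `da` and `db`; because dry biomass
#'     is proportional to wood density, the same ln multiplier shifts the
#'     species' allometric intercept (pioneers are light-wooded);
#'   \item architecture multipliers \eqn{\exp(t_j s)} with
#'     `s = arch_spread` on stature (the height-diameter relation), crown
#'     diameter and crown-base height (pioneers are taller, with broader,
#'     lifted crowns);
#'   \item allometric coefficient offsets \eqn{t_j \cdot spread} on
#'     `(a, b, c)`.
#' }
#' Architecture and density cluster the feature space by species — trees
#' close in the six measured dimensions tend to be conspecific — which is
#' what allows a local, neighbour-based estimator to track the
#' species-specific allometry, while a single global dbh-ht log-linear fit
#' cannot: between the regimes, height and wood density pull biomass in
#' opposite directions.  Exact per-species coefficients may instead be
#' supplied via `species_coef` (no trait multipliers are then applied).
#' All spreads zero reduces to the homogeneous generator (labels only).
#'
#' Auxiliary generation, in detail: `dbh` is lognormal
#' (meanlog `log(8)`, sdlog 0.55) truncated to `dbh_range` by rejection — a
#' right-skewed stand-diameter distribution whose upper range stays
#' populated, as in an even-aged planting where the truncation genuinely
#' bites;
#' `ht = 1.3 + 1.1 dbh^0.75 e^{N(0, 0.15)}` m (within-species
#' height-diameter scatter; between-species stature differences are carried
#' by the architecture multipliers);
#' `dm = 0.45 dbh^0.65 e^{N(0, 0.12)}` m; `hc` is a Beta(6, 15) fraction of
#' `ht` (mean 0.29); `da = 0.62 + 0.006 dbh + N(0, 0.04)` g/cm^3 (floored
#' at 0.35) and `db` is a fraction of `da` between 0.72 and 0.90.  The
#' constraints `hc <= ht` and `db <= da` hold by construction.
#'
#' @param n Number of trees (>= 2).  Default 180.
#' @param coef Global allometric coefficients `c(a, b, c)` on the ln scale.
#' @param sigma Standard deviation of the ln-scale biomass error (>= 0).
#' @param dbh_range Diameter range in cm for the truncated size
#'   distribution.
#' @param n_species Number of species labels; 1 disables heterogeneity.
#' @param spread Across-species standard deviation(s) of the coefficient
#'   offsets, a single value or length-3 vector for `(a, b, c)`, applied
#'   along the contrast ladder.  Ignored when `species_coef` is given.
#' @param density_spread Across-species standard deviation of the ln
#'   wood-density multiplier; shifts each species' intercept by the same
#'   ln multiplier (see Details).  Ignored when `species_coef` is given.
#' @param arch_spread Across-species standard deviation of the ln-scale
#'   architecture multipliers (stature, crown diameter, crown-base height);
#'   see Details.
#' @param species_coef Optional `n_species x 3` matrix of exact per-species
#'   coefficients, overriding `coef`, `spread` and `density_spread` (no
#'   density shift is applied).
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @return A [tree_data] object with `n` records (plus a `species` column
#'   when `n_species > 1`) that passes full validation.
#' @examples
#' ds <- simulate_trees(n = 50, sigma = 0, seed = 1)
#' cf <- c(-1.390796, 1.051491, 1.084280)
#' max(abs(log(ds$w) - (cf[1] + cf[2] * log(ds$dbh) + cf[3] * log(ds$ht))))
#' @export
simulate_trees <- function(n = 180,
                           coef = c(a = -1.390796, b = 1.051491,
                                    c = 1.084280),
                           sigma = 0.3, dbh_range = c(1, 25),
                           n_species = 1, spread = 0, density_spread = 0,
                           arch_spread = 0, species_coef = NULL,
                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    stop("'n' must be a whole number >= 2", call. = FALSE)
  if (length(coef) != 3L || !all(is.finite(coef)))
    stop("'coef' must be three finite values (a, b, c)", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single value >= 0", call. = FALSE)
  if (length(dbh_range) != 2L || dbh_range[1L] <= 0 ||
      dbh_range[2L] <= dbh_range[1L])
    stop("'dbh_range' must be positive and increasing", call. = FALSE)
  if (n_species < 1 || n_species != round(n_species))
    stop("'n_species' must be a positive whole number", call. = FALSE)
  if (!length(spread) %in% c(1L, 3L) || any(spread < 0))
    stop("'spread' must be one or three values >= 0", call. = FALSE)
  spread <- rep_len(spread, 3L)
  if (!is.numeric(density_spread) || length(density_spread) != 1L ||
      density_spread < 0)
    stop("'density_spread' must be a single value >= 0", call. = FALSE)
  if (!is.numeric(arch_spread) || length(arch_spread) != 1L ||
      arch_spread < 0)
    stop("'arch_spread' must be a single value >= 0", call. = FALSE)
  if (!is.null(species_coef)) {
    species_coef <- as.matrix(species_coef)
    if (!identical(dim(species_coef), c(as.integer(n_species), 3L)))
      stop("'species_coef' must be an n_species x 3 matrix", call. = FALSE)
  }
  n <- as.integer(n)

  with_seed(seed, {
    ## right-skewed diameters, truncated by rejection
    dbh <- numeric(0)
    while (length(dbh) < n) {
      cand <- stats::rlnorm(2L * n, meanlog = log(8), sdlog = 0.55)
      dbh <- c(dbh, cand[cand >= dbh_range[1L] & cand <= dbh_range[2L]])
    }
    dbh <- dbh[seq_len(n)]

    ## per-tree multipliers start at 1; species traits modify them below
    ht_mult <- dm_mult <- hc_mult <- dens_mult_i <- rep(1, n)
    species <- NULL
    if (n_species > 1L) {
      species <- sample.int(n_species, n, replace = TRUE)
      if (is.null(species_coef)) {
        ## pioneer -> dense-wood contrast ladder, centred, unit SD
        t_j <- seq_len(n_species) - (n_species + 1) / 2
        t_j <- t_j / sqrt(mean(t_j^2))
        ## light wood for pioneers; dry biomass is proportional to wood
        ## density, so the same ln multiplier enters the intercept
        dens_mult <- exp(-t_j * density_spread)
        ## pioneers: taller stature, broader crowns, lifted crown base
        arch_mult <- exp(t_j * arch_spread)
        species_coef <- cbind(
          coef[1L] + log(dens_mult) + t_j * spread[1L],
          coef[2L] + t_j * spread[2L],
          coef[3L] + t_j * spread[3L])
        ht_mult <- dm_mult <- hc_mult <- arch_mult[species]
        dens_mult_i <- dens_mult[species]
      }
      a_i <- species_coef[species, 1L]
      b_i <- species_coef[species, 2L]
      c_i <- species_coef[species, 3L]
    } else {
      a_i <- coef[1L]; b_i <- coef[2L]; c_i <- coef[3L]
    }

    ht <- 1.3 + 1.1 * ht_mult * dbh^0.75 * exp(stats::rnorm(n, 0, 0.15))
    dm <- 0.45 * dm_mult * dbh^0.65 * exp(stats::rnorm(n, 0, 0.12))
    hc <- ht * pmin(hc_mult * stats::rbeta(n, 6, 15), 0.95)
    da <- pmax(0.62 + 0.006 * dbh + stats::rnorm(n, 0, 0.04), 0.35) *
      dens_mult_i
    db <- da * (0.72 + 0.18 * stats::rbeta(n, 2, 2))

    eps <- if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
    w <- exp(a_i + b_i * log(dbh) + c_i * log(ht) + eps)

    df <- data.frame(dbh = dbh, dm = dm, ht = ht, hc = hc,
                     da = da, db = db, w = w)
    if (!is.null(species)) df$species <- paste0("sp", species)
    tree_data(df, provenance = "synthetic")
  })
}

#' Simulate a heterogeneous (mixed-allometry) synthetic forest
#'
#' Convenience wrapper around [simulate_trees()] for the heterogeneous study
#' condition: several species groups whose allometric coefficients differ,
#' so that no single log-linear equation describes every tree.  Defaults
#' give the classic pioneer versus dense-wood contrast of a two-group
#' restoration planting: 200 trees; allometric exponent offsets of
#' spread 0.35 on `b` and `c` (the two groups' exponents differ by about
#' 0.5); a wood-density contrast of ln-spread 0.2 mirrored in the
#' intercepts; a stature/crown architecture contrast of ln-spread 0.4; and
#' within-species ln-scale noise `sigma = 0.2`.  Under these conditions a
#' global Schumacher-Hall fit attains an original-scale adjusted R-squared
#' of roughly 0.8 — the fit quality typically reported for mixed
#' native-species biomass data — while the exponent contrast leaves it
#' misspecified at both size extremes.
#'
#' @param n,n_species,spread,density_spread,arch_spread,sigma,seed See
#'   [simulate_trees()].
#' @param ... Further arguments passed to [simulate_trees()].
#' @return A [tree_data] object with a `species` column.
#' @export
simulate_mixed_forest <- function(n = 200, n_species = 2,
                                  spread = c(0, 0.35, 0.35),
                                  density_spread = 0.2, arch_spread = 0.4,
                                  sigma = 0.2, seed = NULL, ...) {
  if (n_species < 2)
    stop("a mixed forest needs at least 2 species", call. = FALSE)
  simulate_trees(n = n, n_species = n_species, spread = spread,
                 density_spread = density_spread, arch_spread = arch_spread,
                 sigma = sigma, seed = seed, ...)
}
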