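# knnbiomass

Individual-tree dry biomass estimation for forest inventory, two ways:

* **Instance-based (k-nearest-neighbour) estimation** — a tree's biomass
  is the inverse-distance weighted mean of the biomass of its *k* closest
  trees in predictor space, with four distance metrics (Euclidean,
  quadratic Euclidean, Manhattan, Chebyshev), two weightings (1/d, 1/d²)
  and leave-one-out cross-validation built in.
* **Allometric regression** — the Schumacher–Hall log-linear benchmark,
  ln(w) = a + b·ln(dbh) + c·ln(ht) + e, fitted by OLS, with Shapiro–Wilk,
  White and Durbin–Watson residual diagnostics and optional Baskerville
  back-transformation correction.

Both are judged by one uniform set of model-selection criteria (R²adj,
Syx, AIC, AICc, BIC) on the original biomass scale, compared head-to-head
by the percent reduction in the standard error of estimate (Syx gain), and
benchmarked over full configuration grids (metric × weighting × k ×
predictor subset × transform × data size).  A seeded synthetic-data
generator produces allometric tree datasets — including heterogeneous
two-regime (pioneer vs dense-wood species) forests — so every method is
testable end to end.

The per-tree variables are diameter at breast height (`dbh`, cm), mean
crown diameter (`dm`, m), total height (`ht`, m), height of the lowest
living branch (`hc`, m), apparent and basic wood density (`da`, `db`,
g/cm³), and total dry biomass (`w`, kg).

## Worked example

```r
library(knnbiomass)

ds  <- simulate_mixed_forest(n = 200, seed = 1)   # two-regime forest
fit <- knn_biomass(ds, k = 5, metric = "chebyshev")
fit
#> Nearest-neighbour biomass estimator
#>   200 records, k = 5, chebyshev distance, inv_d weighting
#>   predictors: dbh, dm, ht, hc, da, db
#>   LOOCV (original scale): Syx = 76.12, R2adj = 0.7756

cmp <- compare_to_allometry(ds, k = 5)
cmp
#> Nearest-neighbour estimation vs Schumacher-Hall allometry
#>   kNN: k = 5, inv_d weighting, predictors dbh, dm, ht, hc, da, db
#>   Schumacher-Hall LOO Syx = 77.8 (fitted Syx = 76.15), n = 200
#>
#>               metric   syx r2_adj gain_pct
#>            euclidean 73.37 0.7915    5.697
#>  quadratic_euclidean 82.38 0.7372   -5.888
#>            manhattan 72.34 0.7973    7.018
#>            chebyshev 76.12 0.7756    2.164
#>
#> Best metric by Syx: manhattan

sh_diagnostics(cmp$sh)
#> Residual diagnostics (ln-scale OLS residuals)
#>   Shapiro-Wilk  W  = 0.9904  (p = 0.2065)
#>   White         LM = 23.11  (df = 5, p = 0.0003223)
#>   Durbin-Watson DW = 2.19  (p = 0.1761)
```

Reading this: the kNN configurations predict biomass out-of-sample (LOOCV)
with a standard error of 72–82 kg against the regression's leave-one-out
78 kg, a gain of up to 7 % for this seed; `gain_pct` is the percent Syx
reduction relative to the regression.  The White test flags the
heteroscedasticity that the mixed-species structure induces in the global
log-linear fit — precisely the situation in which local estimation helps.

A neighbourhood sweep shows the characteristic U-shape (one neighbour is
noise-sensitive, many oversmooth):

```r
neighbor_sweep(ds)[, c("k", "syx")]
#>    k    syx
#> 1  1 104.83
#> 2  3  81.74
#> 3  5  76.12
#> 4  7  75.02
#> 5  9  74.53
#> 6 11  76.49
```

Grids run with `run_grid(ds, experiment_grid())`; datasets read and write
as plain CSV via `read_tree_data()` / `write_tree_data()`.  A thin
command-line front end lives at `inst/cli/knnbiomass.R`
(`simulate`, `fit-knn`, `sweep-k`, `run-grid`, `compare`).

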