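# spongeSDM

Presence/absence species distribution modelling (SDM) for deep-sea sponge
grounds and sponge taxa from research-trawl catches and gridded
environmental predictors.

Sponge grounds — dense aggregations of large structure-forming sponges —
are candidate Vulnerable Marine Ecosystems, and mapping where they are
likely to occur is a prerequisite for spatial fisheries management. The
observational basis is awkward: point-wise trawl catches (kg sponge per
standard 1 km tow, georeferenced at the tow start) taken with different
gears in different subareas, and a stack of environmental grids (depth,
slope, chlorophyll-a statistics, modelled bottom/surface temperature,
salinity and current statistics) that are heavily collinear. `spongeSDM`
implements the full pipeline for this setting, for analysts building
trawl-based SDMs and for methodologists studying how such models transfer
between oceanographic regimes:

* **Thresholding** — catch records become sponge-ground presence/absence
  via gear- and subarea-specific weight thresholds (strictly above =
  presence); taxon occurrences use the strict absence rule (absence only
  where no sponges of any kind were caught; unidentified sponge catches are
  excluded from both classes).
* **Layer engineering** — temporal min/mean/max/range statistics with
  strict nodata propagation, bilinear resampling to the common 0.017°
  analysis grid, Horn slope from bathymetry with latitude-corrected cell
  widths, and nearest-cell point extraction.
* **Predictor elimination** — iterative removal of the most-correlated
  pair member while any |R| > 0.5, with a preference ladder (mean first,
  then range, then a per-variable min/max table; annual before seasonal and
  fall before summer chlorophyll; surface before seafloor) and a fully
  auditable trace.
* **Modelling and evaluation** — random forests (500 trees, √p candidate
  splits, vote-fraction probabilities) evaluated by stratified 10-fold
  cross-validation repeated 10 times; fit is AUC, the probability that a
  random presence outscores a random absence (ties at ½):
  AUC = [Σᵢ rank(sᵢ) − n₊(n₊+1)/2] / (n₊ n₋) over presence scores sᵢ.
  Permutation importance is the mean held-out AUC reduction over 10
  shuffles per CV split; partial dependence varies one predictor over its
  observed range with the others fixed at their mean observed values.
* **Prediction and transfer** — per-cell presence-probability rasters, and
  train-in-one-area / test-in-another transfer matrices with
  proxy-predictor ablation (e.g. refitting without depth and slope).
* **Synthetic worlds** — a first-class generator of multi-regime
  environmental stacks and trawl surveys with known ground truth (a
  logistic salinity tolerance at s₀ = 34.5 psu times a shallow depth
  window), designed so collinearity, signal, importance ranking and
  cross-regime proxy failure are all present by construction.

## Worked example

Build a two-regime synthetic world, run elimination, cross-validate a
sponge model in the warm subarea, and recover the salinity tolerance from
partial dependence:

```r
library(spongeSDM)

env <- generateEnvironment(list(warmProxyRegime(), coldProxyRegime()), seed = 1)
env$stack
#> GridStack: 12 layers, 120 x 180 cells
#>   depth, slope, chl_annual_max, chl_summer_max, chl_fall_max, ...

trace <- eliminatePredictors(env$stack)
trace
#> EliminationTrace: 5 eliminated at |R| > 0.50, 7 retained
#>  step                   var_a                   var_b     abs_r
#>     1  temperature_bottom_max temperature_bottom_mean 0.9972734
#>     2 temperature_surface_max  temperature_bottom_max 0.9924661
#>     3     salinity_bottom_min    salinity_bottom_mean 0.9686930
#>     4      current_bottom_max     current_bottom_mean 0.9469817
#>     5          chl_annual_max          chl_summer_max 0.9422213
#>               eliminated            rule
#>  temperature_bottom_mean   metric-ladder
#>  temperature_surface_max stratum-surface
#>     salinity_bottom_mean   metric-ladder
#>      current_bottom_mean   metric-ladder
#>           chl_annual_max   season-annual
#> retained: depth, slope, chl_summer_max, chl_fall_max,
#>   temperature_bottom_max, salinity_bottom_min, current_bottom_max

occ  <- generateOccurrences(env$stack, warmProxyRegime(),
                            surveyConfig(nTows = 600, seed = 2),
                            mask = env$masks[["warm-proxy"]])
pred <- extractAtPoints(env$stack, occ$records)[, retainedPredictors(trace)]

cv <- repeatedCV(occ$records$true_label, pred, k = 10, repeats = 10,
                 seed = 1, ntree = 200)
cv
#> CVResult: 10-fold x 10 repeats (average scoring), mean AUC 0.950

m  <- fitOccurrenceModel(occ$records$true_label, pred, seed = 1)
pd <- partialDependence(m, "salinity_bottom_min", pred)
steepestAscent(pd)
#> [1] 34.39592
```

The elimination trace shows each redundant metric pair collapsing by the
documented rule, leaving seven predictors with all pairwise |R| ≤ 0.5. The
cross-validated AUC of 0.950 is in the "excellent fit" regime expected when
the causal driver is among the predictors, and the steepest ascent of the
salinity partial-dependence curve (34.40 psu) recovers the generating
tolerance threshold (34.5 psu) to about 0.1 psu.

`runFullAnalysis(runConfig(...))` chains every stage — thresholding,
extraction, elimination, per-area CV/importance/partial
dependence/prediction rasters, and the transfer matrix — into one seeded,
cached run whose outputs all carry the configuration hash.

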