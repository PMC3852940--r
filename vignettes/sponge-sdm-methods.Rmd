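---
title: "Methods: random-forest distribution modelling of deep-sea sponge grounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest distribution modelling of deep-sea sponge grounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeSDM)
```

## The problem

Dense aggregations of large structure-forming sponges ("sponge grounds")
are candidate Vulnerable Marine Ecosystems, and spatial fisheries
management needs continuous maps of where they are likely to occur. The
available evidence is point-wise: research-trawl catches, recorded as kg of
sponge per standard 1 km tow at the tow start position, together with
gridded environmental fields (bathymetry and derived slope, surface
chlorophyll-a statistics, and modelled bottom/surface temperature, salinity
and current statistics). `spongeSDM` implements the full presence/absence
species-distribution-modelling pipeline for this setting: catch
thresholding, environmental-layer engineering, collinear-predictor
elimination, random-forest occurrence modelling with cross-validated AUC,
permutation importance and partial dependence, raster prediction, and
cross-area transfer experiments. A synthetic-data module generates
multi-regime worlds with known ground truth so every stage is testable
without access to survey databases.

## From catches to occurrences

A tow is a sponge-ground *presence* iff its catch weight is strictly above
the threshold for its (subarea, gear) pair; equality and everything below
is *absence* ("above the threshold" is read strictly). The packaged
threshold table (`defaultGearThresholds()`) carries the published
kernel-density-derived local thresholds for the Northwest Atlantic
subareas (FC 70 kg for the Campelen 1800 & Lofoten gears; NL 200 kg;
HS/BB 40/70/40 kg for Cosmos/Alfredo/Campelen 1800). For taxon-level
responses, a record is a presence where the taxon was identified, an
absence only where *no sponges of any kind* were caught, and excluded from
both classes where sponges were present but not identified to the taxon —
surveys do not routinely identify sponges below phylum level, so such tows
cannot be scored. Records are assigned to subareas by mask containment
with a first-mask-wins rule (and a warning) on shared boundaries; tows
outside all subareas keep the full-area tag only. A configurable minimum
class size (default 15 presences, the customary smallest class for
attempting species-level models) gates modelling.

## Layer engineering

Grids are a lightweight in-package raster: a matrix in geographic WGS84
coordinates, cell-center registered, row 1 northernmost, with `NA` as
nodata, read and written as plain-text Esri ASCII grids plus a YAML stack
manifest. The analysis grid uses a 0.017 degree cell (about 1 km at the
latitudes of interest). Temporal statistics (min/mean/max/range) reduce a
layer sequence cellwise with *strict* nodata propagation — a cell missing
in any input is missing in every output, avoiding minima and maxima biased
by partial temporal coverage. Resampling to the analysis grid is bilinear
(all fields here are continuous) with conservative nodata: any contributing
source cell missing makes the target cell missing. Slope is derived from
bathymetry by Horn's 8-neighbour gradient with east-west cell widths scaled
by cos(latitude); it is invariant to constant depth offsets, and the
generator pads edges by replication so the slope layer shares the depth
layer's nodata footprint. Point extraction uses the containing cell
(nearest-cell rule): tows are treated as point observations at their start
position, with no along-track averaging even though a tow sweeps about a
kilometre. Out-of-extent points and rows with any missing predictor are
flagged rather than failing the call.

## Predictor elimination

Pearson correlations between all predictor pairs are computed from all
jointly valid raster cells in the study area (a subarea mask is available
for sensitivity runs, because full-area elimination can remove predictors
that are uncorrelated within one subarea). The elimination loop repeatedly
takes the remaining pair with the largest |R| and, while it exceeds 0.5,
removes one member by the first applicable rule:

1. *Metric ladder* — same quantity, different metrics: the mean is
   eliminated first, then the range, then a per-variable min/max preference
   table decides (defaults retain the minimum for bottom salinity — a
   plausible lower tolerance limit — and the maximum for temperature,
   chlorophyll, current and shear). A min-vs-max conflict for a variable
   missing from the table is an error naming the variable.
2. *Season* — annual chlorophyll is eliminated over seasonal; fall over
   summer (summer is closest to the reproductive peak).
3. *Stratum* — sea-surface variables are eliminated in favour of seafloor
   ones.
4. *Tie-break* — the member with the larger mean |R| against all other
   remaining predictors is eliminated (it is the more redundant one);
   the final fallback is lexicographic. Exact ties in "largest |R|" go to
   the first pair in row-major matrix order.

The rule order metric → season → stratum → tie-break is fixed and surfaced
in the trace: each step records the pair, its |R|, the eliminated name and
the rule that fired, so the outcome is fully auditable and re-running on
the same matrix is bit-identical. Undefined correlations (constant layers)
are warned about and ranked as zero. After termination every retained pair
satisfies |R| <= 0.5.

## Occurrence modelling and evaluation

Forests are classification random forests with the reference defaults:
500 trees, floor(sqrt(p)) candidate predictors per split, unpruned trees,
bootstrap samples the size of the training set, no class weighting;
presence probability is the fraction of tree votes. Model fit is the area
under the ROC curve in its Mann-Whitney form — the probability that a
random presence outscores a random absence, ties at one half — computed by
the midrank identity and verified in the tests against exhaustive pairwise
counting.

Cross-validation is 10-fold repeated 10 times. Folds are stratified by
class (the absence class can outnumber presences twenty-fold; unstratified
folds could produce single-class test sets). The headline statistic is the
mean of per-fold AUCs; pooled scoring over all out-of-fold predictions is
available as an option, and is the only defined choice when folds are too
small to stratify (e.g. leave-one-out).

Permutation importance is measured on the AUC scale, per cross-validation
split: a predictor's held-out values are shuffled 10 times per split and
the importance is the mean reduction in held-out AUC, so results do not
hinge on a particular split or permutation. Importance of correlated
predictors is diluted across the group (the sum of importances is not
constrained); values are descriptive and no hypothesis tests are
performed. For reporting, reductions are conventionally displayed as
AUC reduction x 100 and entries below 0.01 are not listed.

Partial dependence here is the *single-point* variant: one synthetic
observation whose other covariates are fixed at their mean observed values,
with the focal predictor varied over a 100-point grid spanning its observed
range. This matches how the curves in this analysis style are produced; the
dataset-averaged (Friedman) variant is available behind the
`average = TRUE` flag for comparison. `steepestAscent()` locates the
maximum positive slope of the (lightly smoothed) curve — the model-implied
lower tolerance threshold when the response is a rising sigmoid.

Raster prediction applies the model cellwise, with nodata wherever any
predictor is nodata; a cell-center point prediction equals the raster value
of that cell by construction.

## Transfer experiments

Within-area fit (the matrix diagonal) is the repeated-CV mean. Cross-area
fit trains one forest on *all* training-area records — no cross-validation,
since the test area is disjoint — and scores it on the test area's labels.
The matrix is not symmetric in general. `proxyAblation()` re-runs a
transfer with a suspected proxy set (by default depth and slope) removed
from the training data, with the same seed, returning the paired AUCs.
Elimination is performed once on the full-area stack and shared by all
cells, with a per-area option for sensitivity analyses.

## The synthetic world

The generator builds the smallest world that exhibits the phenomena the
pipeline must detect. Two subareas ("warm-proxy", "cold-proxy") occupy
adjacent longitude bands of one co-registered stack (120 x 90 cells per
band at 0.017 degrees, ~10,800 cells per subarea so correlation designs are
estimated tightly). Both share the same *causal* response of the simulated
taxon:

p(presence) = plogis(steepness * (Smin - s0)) * plogis((depth - 150) / 40)

with s0 = 34.5 psu (the centre of the 34.3-34.8 psu range where a lower
salinity tolerance for these sponges is hypothesised) and steepness
12 psu^-1, so the transition occupies roughly a third of a psu. The depth
window suppresses presence only at the shallowest stations (cutoff 150 m,
width 40 m). This window is deliberately shallow-biting: with a deeper
cutoff the cold regime's response would be non-monotone in salinity over
most sampled depths (its shallow water is its saltiest), and no salinity-led
model could transfer there — the design intent is that the causal response
itself transfers and only the proxies mislead.

What differs between regimes is how depth maps to the other variables.
Maximum bottom temperature follows a per-regime mapping — warm: linear,
about 12 degC near surface falling to 5.5 degC at 1800 m; cold: a sigmoid
from 1.5 degC shallow to 0.6 degC deep, below 1 degC past ~1500 m — so the
same depth means different temperatures in different subareas, and a
mapping fitted in one regime mispredicts the other badly. Minimum bottom
salinity trends *upward* with depth in the warm regime and *downward* in
the cold one (half-amplitude 0.5 psu plus a smooth 0.12 psu texture field).
Within a regime, depth is therefore an excellent proxy for the causal
driver; across regimes it actively misleads; and pooled over the full area
the opposing trends cancel, which is why full-area elimination retains both
depth and salinity (|R| well under 0.5) — the same mechanism by which
full-area elimination can be locally suboptimal.

Redundant metric families are built with designed correlation: the mean of
a quantity is its min/max plus a small offset and noise (|R| > 0.9), annual
chlorophyll is 0.8 x summer plus noise, surface temperature is bottom
temperature plus noise; independently generated fields (summer vs fall
chlorophyll, current, salinity) stay below |R| 0.3. With the default
preference ladder, elimination reduces the 12-layer stack to exactly
`designedRetainedSet()`: depth, slope, summer and fall chlorophyll maxima,
maximum bottom temperature, minimum bottom salinity, maximum bottom
current.

Surveys sample tow positions uniformly over a subarea's cells at depths
<= 1800 m (the survey depth restriction), 600 tows per subarea by default.
True labels are Bernoulli draws from the causal response (plus a small
response-scale noise, sd 0.02). On-deck catch weights are lognormal for
presences (log-mean log 300 kg, log-sd 1.2) and zero-inflated exponential
for absences (70% zeros, mean 20 kg otherwise), scaled by catchability;
with a fixed seed, changing catchability rescales weights without touching
positions or labels. Against a 70 kg threshold these distributions give
closed-form confusion rates (`thresholdConfusionRates()`: about 11% false
absences, 1% false presences) that the tests verify empirically.

What the generator does *not* emulate: spatial autocorrelation of tows
beyond the smoothness of the fields, patchiness of sponges within a cell,
ice cover, realistic ocean physics, gear-specific swept areas, or
detectability. Passing tests therefore show the machinery is correct and
that the designed effects are recovered under ideal sampling; they do not
certify performance on real survey data, where detection error and sampling
bias add failure modes this world does not contain.

## Numerical choices and experiment sizes

All stochastic operations are pure functions of their seed. Tests and the
acceptance script size experiments for desk-scale runs: cross-validation
sweeps use 100-200 trees per forest (the fit itself defaults to 500;
reduced forests only widen Monte-Carlo noise slightly in CV means), the
chance-level calibration uses 200-tow surveys over 20 seeds, and the
signal, importance, tolerance-recovery and transfer experiments use the
default 600-tow surveys over 10 seeds. The directional ablation comparison
averages three replicate 500-tree fits per world because the forest-fit
noise (~0.02 AUC) is comparable to the ablation effect in worlds that
happen to transfer well. In about 2 of 10 worlds the full model transfers
well enough that removing depth and slope does not help — an honest
property of stochastic worlds, visible in the tests' 8/10 direction count.

Degenerate inputs are handled explicitly: single-class responses, missing
predictor layers and missing thresholds are named errors; constant layers
yield warned-undefined correlations ranked as zero; zero-variance
predictors give single-point partial-dependence curves with a warning;
out-of-extent points are flagged per point, not fatal.

## Limitations

The raster layer is deliberately minimal (geographic WGS84 only, square
cells, no projections, single-band text files). Partial dependence at
covariate means can sit in unrealistic covariate combinations when
predictors are strongly correlated — that is inherent to the single-point
variant and a reason the averaged variant is also provided. Permutation
importance under correlated predictors divides credit; it identifies the
causal variable only up to its proxy group. The transfer experiments share
one elimination across areas by default; per-area elimination can change
retained sets and is available but not the default.
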