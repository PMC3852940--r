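Package: spongeSDM
Title: Random-Forest Distribution Modelling of Deep-Sea Sponge Grounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence/absence species distribution modelling for deep-sea
    sponge grounds and sponge taxa from research-trawl catch records and
    gridded environmental predictors. Implements trawl-catch thresholding
    with gear- and subarea-specific cutoffs, environmental-layer engineering
    (temporal statistics, bilinear resampling, slope from bathymetry, point
    extraction), iterative pairwise-correlation predictor elimination with an
    ecologically motivated preference ladder, random-forest occurrence models
    evaluated by repeated stratified cross-validated AUC, per-split
    permutation importance on the AUC scale, partial dependence at mean
    observed covariate values, raster prediction, and train-in-one-area /
    test-in-another transfer experiments with proxy-predictor ablation.
    Includes a synthetic-data module that simulates multi-regime
    environmental grids and trawl surveys with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
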