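# Synthetic-data generator: determinism, designed correlation structure,
# regime contrasts, survey truth and scaling contracts.

test_that("environment generation is a pure function of (configs, seed)", {
  regimes <- list(warmProxyRegime(), coldProxyRegime())
  e1 <- generateEnvironment(regimes, seed = 5)
  e2 <- generateEnvironment(regimes, seed = 5)
  for (nm in gridNames(e1$stack))
    expect_identical(gridValues(e1$stack[[nm]]), gridValues(e2$stack[[nm]]))
  e3 <- generateEnvironment(regimes, seed = 6)
  expect_false(identical(gridValues(e3$stack[["depth"]]),
                         gridValues(e1$stack[["depth"]])))
})

test_that("generator rejects bad configurations", {
  expect_error(generateEnvironment(list(), seed = 1), "at least one")
  expect_error(
    generateEnvironment(list(warmProxyRegime(), warmProxyRegime()),
                        seed = 1),
    "overlap")
  expect_error(
    generateEnvironment(list(warmProxyRegime()),
                        gridSpec = list(nrow = 10L, ncolPerRegime = 10L,
                                        cellSize = -1, origin = c(0, 0)),
                        seed = 1),
    "cell size")
  expect_error(regimeConfig("x", salinityMidpoint = 20), "span")
  expect_error(surveyConfig(catchability = 0), "catchability")
})

test_that("designed redundant pairs exceed |R| 0.5 and independents stay low", {
  w <- syntheticWorld(21)
  st <- w$env$stack
  r <- function(a, b) {
    va <- as.vector(gridValues(st[[a]])); vb <- as.vector(gridValues(st[[b]]))
    ok <- !is.na(va) & !is.na(vb)
    cor(va[ok], vb[ok])
  }
  redundant <- list(c("salinity_bottom_min", "salinity_bottom_mean"),
                    c("temperature_bottom_max", "temperature_bottom_mean"),
                    c("temperature_bottom_max", "temperature_surface_max"),
                    c("chl_annual_max", "chl_summer_max"),
                    c("current_bottom_max", "current_bottom_mean"))
  for (p in redundant) expect_gt(abs(r(p[1], p[2])), 0.5)
  independent <- list(c("chl_summer_max", "chl_fall_max"),
                      c("chl_summer_max", "salinity_bottom_min"),
                      c("current_bottom_max", "salinity_bottom_min"),
                      c("chl_fall_max", "current_bottom_max"))
  for (p in independent) expect_lt(abs(r(p[1], p[2])), 0.3)
  # enough cells for the correlation design to be meaningful
  expect_gte(sum(!is.na(gridValues(st[["depth"]]))), 10000)
})

test_that("regimes map the same depth to different temperatures", {
  warm <- warmProxyRegime(); cold <- coldProxyRegime()
  d <- seq(100, 1800, by = 25)
  tw <- evalTempOfDepth(warm$temp_of_depth, d)
  tc <- evalTempOfDepth(cold$temp_of_depth, d)
  expect_lt(cor(tw, tc), 1 - 1e-6)   # mappings genuinely disagree in shape
  deep <- d > 1500
  expect_true(all(tc[deep] > 0 & tc[deep] < 1))  # cold basin: 0-1 degC deep
  expect_true(all(tw[deep] > 4))
  # cross-regime misprediction of maxTemp is bounded away from zero
  rmse <- sqrt(mean((tw - tc)^2))
  expect_gt(rmse, 1)
})

test_that("per-subarea depth-temperature scatter reflects its regime", {
  w <- syntheticWorld(21)
  st <- w$env$stack
  for (rg in w$env$regimes) {
    m <- !is.na(gridValues(w$env$masks[[rg$subarea_name]]))
    d <- gridValues(st[["depth"]])[m]
    t <- gridValues(st[["temperature_bottom_max"]])[m]
    pred <- evalTempOfDepth(rg$temp_of_depth, d)
    expect_lt(sqrt(mean((t - pred)^2)), 1)   # own mapping fits
  }
  # warm mapping applied in the cold subarea mispredicts badly
  mC <- !is.na(gridValues(w$env$masks[["cold-proxy"]]))
  dC <- gridValues(st[["depth"]])[mC]
  tC <- gridValues(st[["temperature_bottom_max"]])[mC]
  wrong <- evalTempOfDepth(warmProxyRegime()$temp_of_depth, dC)
  expect_gt(sqrt(mean((tC - wrong)^2)), 2)
})

test_that("masks align with the stack and probabilities are conserved", {
  w <- syntheticWorld(21)
  st <- w$env$stack
  naPattern <- is.na(gridValues(st[[1]]))
  for (nm in gridNames(st))
    expect_identical(is.na(gridValues(st[[nm]])), naPattern)
  pg <- gridValues(w$areas[["warm-proxy"]]$survey$truth$probability)
  expect_true(all(pg >= 0 & pg <= 1, na.rm = TRUE))
})

test_that("a saturated response yields all-presence tows", {
  env <- generateEnvironment(list(warmProxyRegime()), seed = 3)
  steep <- regimeConfig("warm-proxy", salinitySteepness = 500,
                        salinityMidpoint = 34.05, depthCutoff = 60,
                        depthWidth = 5, noiseSD = 0)
  occ <- generateOccurrences(env$stack, steep,
                             surveyConfig(nTows = 300, seed = 11),
                             mask = env$masks[["warm-proxy"]])
  sal <- extractAtPoints(env$stack, occ$records)$salinity_bottom_min
  high <- sal > 34.2   # tows far above the midpoint, inside depth window
  expect_gt(sum(high), 50)
  expect_true(all(occ$records$true_label[high]))
})

test_that("empirical presence fraction matches the generating probabilities", {
  env <- generateEnvironment(list(warmProxyRegime()), seed = 8)
  occ <- generateOccurrences(env$stack, warmProxyRegime(),
                             surveyConfig(nTows = 5000, seed = 12),
                             mask = env$masks[["warm-proxy"]])
  pbar <- mean(occ$truth$tow_probability)
  n <- 5000
  ci <- qbinom(c(0.025, 0.975), n, pbar) / n   # exact binomial bound
  frac <- mean(occ$records$true_label)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("catchability rescales weights without touching labels", {
  env <- generateEnvironment(list(warmProxyRegime()), seed = 4)
  occ1 <- generateOccurrences(env$stack, warmProxyRegime(),
                              surveyConfig(nTows = 400, seed = 9,
                                           catchability = 1),
                              mask = env$masks[["warm-proxy"]])
  occ2 <- generateOccurrences(env$stack, warmProxyRegime(),
                              surveyConfig(nTows = 400, seed = 9,
                                           catchability = 0.02),
                              mask = env$masks[["warm-proxy"]])
  expect_identical(occ1$records$true_label, occ2$records$true_label)
  expect_identical(occ1$records$lon, occ2$records$lon)
  expect_equal(occ2$records$sponge_weight_kg,
               occ1$records$sponge_weight_kg * 0.02)
})

test_that("survey respects the depth restriction and required layers", {
  env <- generateEnvironment(list(warmProxyRegime()), seed = 4)
  occ <- generateOccurrences(env$stack, warmProxyRegime(),
                             surveyConfig(nTows = 500, seed = 2,
                                          maxSampleDepth = 800),
                             mask = env$masks[["warm-proxy"]])
  d <- extractAtPoints(env$stack, occ$records)$depth
  expect_true(all(d <= 800))
  noSal <- GridStack(env$stack[["depth"]])
  expect_error(
    generateOccurrences(noSal, warmProxyRegime(),
                        surveyConfig(nTows = 10, seed = 1)),
    "salinity_bottom_min")
})

test_that("synthetic survey writes plain-text tows and truth sidecar", {
  env <- generateEnvironment(list(warmProxyRegime()), seed = 4)
  occ <- generateOccurrences(env$stack, warmProxyRegime(),
                             surveyConfig(nTows = 50, seed = 2),
                             mask = env$masks[["warm-proxy"]])
  d <- withr::local_tempdir()
  writeSyntheticSurvey(occ, d, stem = "s")
  tows <- read.csv(file.path(d, "s_tows.csv"))
  expect_equal(nrow(tows), 50)
  truth <- jsonlite::read_json(file.path(d, "s_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$regime$s0, 34.5)
  expect_equal(length(truth$tow_label), 50)
})
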