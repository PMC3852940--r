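# Synthetic-data module: multi-regime environmental grid stacks and trawl
# surveys with known ground truth. The generator's defaults define the study
# conditions for every downstream validation experiment: two subareas share
# the same causal response (a logistic tolerance in minimum bottom salinity
# times a smooth depth window) but differ in how depth maps to temperature
# and salinity, so that proxy predictors work within a regime and mislead
# across regimes.

#' Configure an oceanographic regime for the synthetic generator
#'
#' A regime describes one subarea: its depth span, the true salinity
#' tolerance of the simulated taxon, the depth window, and two per-regime
#' depth mappings (to maximum bottom temperature, and to the spatial trend
#' of minimum bottom salinity) that give proxy predictors their
#' regime-specific behaviour.
#'
#' @param subareaName subarea label.
#' @param depthRange c(min, max) sampled depth in meters.
#' @param salinityMidpoint true tolerance threshold s0 (psu): presence
#'   probability is logistic in (Smin - s0).
#' @param salinitySteepness logistic steepness (psu^-1), > 0.
#' @param depthCutoff shallow cutoff (m) of the smooth depth window.
#' @param depthWidth width (m) of the depth window's logistic edge.
#' @param tempOfDepth monotone depth-to-maximum-bottom-temperature mapping:
#'   \code{list(type = "linear", intercept, slope)} or
#'   \code{list(type = "sigmoid", base, amplitude, midpoint, width)}.
#' @param salinityDepthGain half-amplitude (psu) of the linear depth trend in
#'   minimum bottom salinity across the regime's depth span; its sign decides
#'   whether depth proxies salinity positively or negatively in the regime.
#' @param noiseSD response-scale (probability) noise added to the true
#'   presence probability before the Bernoulli draw.
#' @return a validated list of class "RegimeConfig".
#' @export
regimeConfig <- function(subareaName,
                         depthRange = c(50, 1800),
                         salinityMidpoint = 34.5,
                         salinitySteepness = 12,
                         depthCutoff = 150,
                         depthWidth = 40,
                         tempOfDepth = list(type = "linear",
                                            intercept = 12, slope = -0.0036),
                         salinityDepthGain = 0.5,
                         noiseSD = 0.02) {
  stopifnot(length(depthRange) == 2L, depthRange[1] < depthRange[2],
            salinitySteepness > 0, depthWidth > 0, noiseSD >= 0)
  span <- abs(salinityDepthGain) + 0.25   # field half-span incl. texture
  if (salinityMidpoint < 34.5 - span || salinityMidpoint > 34.5 + span)
    stop("salinityMidpoint must lie within the generated salinity span")
  structure(list(subarea_name = subareaName, depth_range = depthRange,
                 s0 = salinityMidpoint, steepness = salinitySteepness,
                 depth_cutoff = depthCutoff, depth_width = depthWidth,
                 temp_of_depth = tempOfDepth,
                 salinity_depth_gain = salinityDepthGain,
                 noise_sd = noiseSD),
            class = "RegimeConfig")
}

#' Default "warm-proxy" regime
#'
#' Warm continental-slope regime: maximum bottom temperature decreases
#' roughly linearly with depth from about 12 degC near the surface, and
#' minimum bottom salinity increases with depth, so depth is a strong
#' positive proxy for the causal salinity driver.
#' @return a "RegimeConfig".
#' @export
warmProxyRegime <- function() regimeConfig("warm-proxy")

#' Default "cold-proxy" regime
#'
#' Cold basin regime: bottom water is cold throughout, dropping towards
#' 0-1 degC at depth through a sigmoidal depth-temperature relationship, and
#' minimum bottom salinity decreases with depth — the opposite proxy
#' relationship to the warm regime, while the causal salinity response of
#' the taxon is identical.
#' @return a "RegimeConfig".
#' @export
coldProxyRegime <- function()
  regimeConfig("cold-proxy",
               tempOfDepth = list(type = "sigmoid", base = 0.6,
                                  amplitude = 0.9, midpoint = 900,
                                  width = 150),
               salinityDepthGain = -0.5)

#' Evaluate a regime's depth-to-temperature mapping
#'
#' @param tempOfDepth mapping spec (see \code{\link{regimeConfig}}).
#' @param depth depth in meters (vector).
#' @return temperature in degC.
#' @export
evalTempOfDepth <- function(tempOfDepth, depth) {
  switch(tempOfDepth$type,
    linear = tempOfDepth$intercept + tempOfDepth$slope * depth,
    sigmoid = tempOfDepth$base + tempOfDepth$amplitude *
      stats::plogis((tempOfDepth$midpoint - depth) / tempOfDepth$width),
    stop("unknown temp_of_depth type: ", tempOfDepth$type))
}

#' Configure a synthetic trawl survey
#'
#' @param nTows number of tows, > 0.
#' @param gear gear label attached to every record.
#' @param catchability fraction in (0, 1] scaling all on-deck weights.
#' @param presenceMeanlog,presenceSdlog log-scale parameters of the
#'   lognormal catch-weight distribution at true-presence tows (kg/tow at
#'   catchability 1).
#' @param absenceZeroProb probability of a zero catch at a true-absence tow.
#' @param absenceRate exponential rate (1/kg) of nonzero absence catches.
#' @param maxSampleDepth tows are restricted to depths below this (m),
#'   mirroring survey depth limits.
#' @param seed RNG seed; the survey is a pure function of (configs, seed).
#' @return a validated list of class "SurveyConfig".
#' @export
surveyConfig <- function(nTows = 600, gear = "Campelen 1800",
                         catchability = 1,
                         presenceMeanlog = log(300), presenceSdlog = 1.2,
                         absenceZeroProb = 0.7, absenceRate = 1 / 20,
                         maxSampleDepth = 1800, seed = 1L) {
  stopifnot(nTows > 0, catchability > 0, catchability <= 1,
            maxSampleDepth > 0, absenceZeroProb >= 0, absenceZeroProb <= 1,
            absenceRate > 0)
  structure(list(n_tows = as.integer(nTows), gear = gear,
                 catchability = catchability,
                 presence_meanlog = presenceMeanlog,
                 presence_sdlog = presenceSdlog,
                 absence_zero_prob = absenceZeroProb,
                 absence_rate = absenceRate,
                 max_sample_depth = maxSampleDepth, seed = as.integer(seed)),
            class = "SurveyConfig")
}

# Gaussian-smoothed random field with approximately unit variance, rescaled
# to sd; 'scale' is the smoothing kernel sd in cells.
smoothField <- function(nr, nc, scale = 6, sd = 1) {
  half <- 2L * scale
  pad <- half + 1L
  m <- matrix(rnorm((nr + 2L * pad) * (nc + 2L * pad)), nr + 2L * pad)
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  sm <- apply(m, 2L, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1L, function(row) stats::filter(row, k, sides = 2)))
  sm <- sm[(pad + 1L):(pad + nr), (pad + 1L):(pad + nc)]
  sm * (sd / stats::sd(as.vector(sm)))
}

# Horn slope with edge replication so the slope layer has the same nodata
# footprint as the depth layer it derives from.
slopePadded <- function(depth) {
  z <- depth@values
  zp <- rbind(z[1L, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  zp <- cbind(zp[, 1L, drop = FALSE], zp, zp[, ncol(zp), drop = FALSE])
  gp <- Grid(zp, depth@origin + c(-depth@cellSize, depth@cellSize),
             depth@cellSize, "depth_padded", "m")
  s <- slopeFromDepth(gp)
  Grid(s@values[2:(nrow(zp) - 1L), 2:(ncol(zp) - 1L)],
       depth@origin, depth@cellSize, "slope", "degrees")
}

#' Generate a multi-regime synthetic environmental grid stack
#'
#' Builds one co-registered predictor stack covering all regimes as adjacent
#' longitude bands, plus one subarea mask per regime. Emitted layers mimic
#' the standard families used in trawl-based sponge SDM: depth, slope,
#' seasonal/annual chlorophyll metrics, and bottom/surface temperature,
#' salinity and current metrics. Redundant metric pairs (mean vs max, annual
#' vs summer, surface vs bottom) are generated with designed pairwise
#' |R| > 0.5 so that correlation-based elimination is exercised;
#' independently generated fields stay below |R| < 0.3. Temperature follows
#' each regime's depth mapping, so the same depth maps to different
#' temperatures in different subareas.
#'
#' @param regimes non-empty list of \code{\link{regimeConfig}} objects with
#'   distinct subarea names.
#' @param gridSpec list with \code{nrow}, \code{ncolPerRegime},
#'   \code{cellSize} (degrees, > 0), \code{origin} (lon/lat of the NW cell
#'   center).
#' @param seed RNG seed; output is a pure function of (configs, seed).
#' @return list with elements \code{stack} (\code{\link{GridStack}}),
#'   \code{masks} (named list of 1/NA \code{Grid} masks, one per regime) and
#'   \code{regimes}.
#' @export
generateEnvironment <- function(regimes,
                                gridSpec = list(nrow = 120L,
                                                ncolPerRegime = 90L,
                                                cellSize = 0.017,
                                                origin = c(-60, 48)),
                                seed = 1L) {
  if (length(regimes) == 0L) stop("at least one regime is required")
  nms <- vapply(regimes, function(r) r$subarea_name, character(1))
  if (anyDuplicated(nms))
    stop("regime subarea names overlap: ", nms[duplicated(nms)][1L])
  if (gridSpec$cellSize <= 0) stop("cell size must be positive")
  set.seed(as.integer(seed))
  nr <- as.integer(gridSpec$nrow)
  ncR <- as.integer(gridSpec$ncolPerRegime)
  nc <- ncR * length(regimes)
  cs <- gridSpec$cellSize
  org <- gridSpec$origin
  mk <- function(name, units, v) Grid(v, org, cs, name, units)
  empty <- function() matrix(NA_real_, nr, nc)

  depth <- empty(); tempB <- empty(); salMin <- empty()
  masks <- list()
  for (ri in seq_along(regimes)) {
    rg <- regimes[[ri]]
    cols <- ((ri - 1L) * ncR + 1L):(ri * ncR)
    dr <- rg$depth_range
    # north-to-south bathymetric ramp plus smooth multi-scale relief
    ramp <- matrix(seq(dr[1], dr[2], length.out = nr), nr, ncR)
    relief <- 150 * smoothField(nr, ncR, scale = 4) +
      60 * smoothField(nr, ncR, scale = 2)
    d <- pmin(pmax(ramp + relief, dr[1]), dr[2])
    depth[, cols] <- d
    tempB[, cols] <- evalTempOfDepth(rg$temp_of_depth, d) +
      0.3 * smoothField(nr, ncR, scale = 5)
    mid <- mean(dr); half <- diff(dr) / 2
    salMin[, cols] <- rg$s0 +
      rg$salinity_depth_gain * (d - mid) / half +
      0.12 * smoothField(nr, ncR, scale = 5)
    m <- empty(); m[, cols] <- 1
    masks[[rg$subarea_name]] <- mk(paste0("mask_", rg$subarea_name), "", m)
  }

  depthG <- mk("depth", "m", depth)
  chlSummer <- pmax(1.5 + smoothField(nr, nc, scale = 6, sd = 0.5), 0.05)
  chlAnnual <- pmax(0.8 * chlSummer + 0.3 +
                      smoothField(nr, nc, scale = 6, sd = 0.15), 0.05)
  chlFall <- pmax(1.0 + smoothField(nr, nc, scale = 6, sd = 0.4), 0.05)
  tempMean <- tempB - 1.0 + smoothField(nr, nc, scale = 5, sd = 0.3)
  tempSurf <- tempB + 2.0 + smoothField(nr, nc, scale = 5, sd = 0.5)
  salMean <- salMin + 0.25 + smoothField(nr, nc, scale = 5, sd = 0.08)
  curMax <- pmax(0.15 + smoothField(nr, nc, scale = 5, sd = 0.05), 0.005)
  curMean <- pmax(0.6 * curMax - 0.02 +
                    smoothField(nr, nc, scale = 5, sd = 0.01), 0.002)

  stack <- GridStack(
    depthG,
    slopePadded(depthG),
    mk("chl_annual_max", "mg m-3", chlAnnual),
    mk("chl_summer_max", "mg m-3", chlSummer),
    mk("chl_fall_max", "mg m-3", chlFall),
    mk("temperature_surface_max", "degC", tempSurf),
    mk("temperature_bottom_max", "degC", tempB),
    mk("temperature_bottom_mean", "degC", tempMean),
    mk("salinity_bottom_min", "psu", salMin),
    mk("salinity_bottom_mean", "psu", salMean),
    mk("current_bottom_max", "m s-1", curMax),
    mk("current_bottom_mean", "m s-1", curMean))
  list(stack = stack, masks = masks, regimes = regimes)
}

#' Predictors the default synthetic stack is designed to retain
#'
#' The redundant metric pairs built into \code{\link{generateEnvironment}}
#' are designed so that correlation-based elimination at |R| > 0.5 with the
#' default preference ladder reduces the stack to exactly this set.
#' @return character vector of predictor names.
#' @export
designedRetainedSet <- function() {
  c("depth", "slope", "chl_summer_max", "chl_fall_max",
    "temperature_bottom_max", "salinity_bottom_min", "current_bottom_max")
}

#' True per-cell presence probability under a regime
#'
#' The causal response: a logistic tolerance in minimum bottom salinity,
#' p = plogis(steepness * (Smin - s0)), multiplied by a smooth depth window
#' plogis((depth - depthCutoff) / depthWidth) that suppresses presence in
#' shallow water.
#'
#' @param regime a "RegimeConfig".
#' @param salMin minimum bottom salinity (psu, vector or matrix).
#' @param depth depth (m), same shape.
#' @return presence probability in [0, 1], same shape.
#' @export
truePresenceProbability <- function(regime, salMin, depth) {
  stats::plogis(regime$steepness * (salMin - regime$s0)) *
    stats::plogis((depth - regime$depth_cutoff) / regime$depth_width)
}

#' Simulate a trawl survey over a synthetic subarea
#'
#' Samples tow positions uniformly over the subarea's valid cells at depths
#' not exceeding the survey's depth limit, draws true presence labels from
#' the regime's causal response evaluated at the sampled cells, and draws
#' on-deck catch weights from a lognormal (presence) or zero-inflated
#' exponential (absence) distribution scaled by catchability. With identical
#' seeds, changing catchability rescales weights but leaves positions and
#' labels untouched.
#'
#' @param stack \code{\link{GridStack}} containing at least the layers
#'   \code{salinity_bottom_min} and \code{depth}.
#' @param regime a "RegimeConfig".
#' @param survey a "SurveyConfig" (its \code{seed} drives all randomness).
#' @param mask optional 1/NA \code{Grid} restricting the sampled subarea;
#'   default: all valid cells.
#' @return list with \code{records} (data.frame: tow_id, lon, lat, gear,
#'   subarea, sponge_weight_kg, true_label, total_sponge_present) and
#'   \code{truth} (per-cell probability \code{Grid}, per-tow probabilities,
#'   generating-parameter echo).
#' @export
generateOccurrences <- function(stack, regime, survey, mask = NULL) {
  for (need in c("salinity_bottom_min", "depth"))
    if (!(need %in% gridNames(stack)))
      stop("required layer missing from stack: ", need)
  depthG <- stack[["depth"]]
  salG <- stack[["salinity_bottom_min"]]
  ok <- !is.na(depthG@values) & !is.na(salG@values) &
    depthG@values <= survey$max_sample_depth
  if (!is.null(mask)) ok <- ok & !is.na(mask@values)
  cells <- which(ok)
  if (length(cells) == 0L) stop("no sampleable cells in the subarea")

  probGridV <- matrix(NA_real_, nrow(depthG@values), ncol(depthG@values))
  probGridV[ok] <- truePresenceProbability(
    regime, salG@values[ok], depthG@values[ok])

  set.seed(survey$seed)
  n <- survey$n_tows
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  cs <- depthG@cellSize
  nr <- nrow(depthG@values)
  i <- ((pick - 1L) %% nr) + 1L
  j <- ((pick - 1L) %/% nr) + 1L
  lon <- depthG@origin[1] + (j - 1L) * cs + runif(n, -cs / 2, cs / 2) * 0.98
  lat <- depthG@origin[2] - (i - 1L) * cs + runif(n, -cs / 2, cs / 2) * 0.98

  p <- truePresenceProbability(regime, salG@values[pick], depthG@values[pick])
  if (regime$noise_sd > 0)
    p <- pmin(pmax(p + rnorm(n, 0, regime$noise_sd), 0), 1)
  label <- rbinom(n, 1L, p) == 1L
  # weight draws consume the same randomness regardless of catchability or
  # labels, so catchability is a pure scaling with a shared seed
  wPres <- rlnorm(n, survey$presence_meanlog, survey$presence_sdlog)
  wAbs <- ifelse(runif(n) < survey$absence_zero_prob, 0,
                 rexp(n, survey$absence_rate))
  w <- survey$catchability * ifelse(label, wPres, wAbs)

  records <- data.frame(
    tow_id = sprintf("%s_%04d", regime$subarea_name, seq_len(n)),
    lon = lon, lat = lat, gear = survey$gear,
    subarea = regime$subarea_name,
    sponge_weight_kg = w, true_label = label,
    total_sponge_present = w > 0,
    stringsAsFactors = FALSE)
  truth <- list(
    probability = Grid(probGridV, depthG@origin, cs,
                       paste0("true_probability_", regime$subarea_name), ""),
    tow_probability = p, tow_label = label,
    params = list(regime = regime, survey = survey))
  list(records = records, truth = truth)
}

#' Closed-form confusion rates of threshold classification
#'
#' Under the synthetic catch-weight model, the probability that a
#' true-presence tow falls at or below the threshold (false absence) is the
#' lognormal CDF at threshold / catchability, and the probability that a
#' true-absence tow exceeds it (false presence) is
#' (1 - zeroProb) * exp(-rate * threshold / catchability).
#'
#' @param survey a "SurveyConfig".
#' @param threshold classification threshold (kg/tow, on-deck scale).
#' @return list with \code{false_absence} and \code{false_presence}.
#' @export
thresholdConfusionRates <- function(survey, threshold) {
  t0 <- threshold / survey$catchability
  list(false_absence = stats::plnorm(t0, survey$presence_meanlog,
                                     survey$presence_sdlog),
       false_presence = (1 - survey$absence_zero_prob) *
         exp(-survey$absence_rate * t0))
}

#' Write synthetic survey outputs to disk
#'
#' Emits the tow records as CSV (columns tow_id, lon, lat, gear,
#' sponge_weight_kg, true_label) and the generating truth as a JSON sidecar.
#'
#' @param occ result of \code{\link{generateOccurrences}}.
#' @param dir output directory.
#' @param stem file-name stem.
#' @export
writeSyntheticSurvey <- function(occ, dir, stem = "survey") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(occ$records, file.path(dir, paste0(stem, "_tows.csv")),
            row.names = FALSE)
  pr <- occ$truth$params$regime
  sv <- occ$truth$params$survey
  jsonlite::write_json(
    list(regime = unclass(pr), survey = unclass(sv),
         tow_probability = occ$truth$tow_probability,
         tow_label = occ$truth$tow_label),
    file.path(dir, paste0(stem, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
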