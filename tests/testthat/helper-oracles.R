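# Independent test-side oracles and shared fixtures.

# Exhaustive pairwise-counting AUC: the probability a random presence
# outscores a random absence, ties at weight 1/2. Independent of the
# package's midrank implementation.
bruteForceAUC <- function(scores, presence) {
  s1 <- scores[presence]; s0 <- scores[!presence]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}

# Hand-rolled Pearson correlation from the defining formula.
pearsonByHand <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# A planar ramp grid: value = a + bLon * lon + bLat * lat at cell centers.
planarRampGrid <- function(nr = 12, nc = 15, a = 0, bLon = 1, bLat = 0,
                           origin = c(0, 1), cs = 0.1, name = "ramp") {
  lons <- origin[1] + (seq_len(nc) - 1L) * cs
  lats <- origin[2] - (seq_len(nr) - 1L) * cs
  Grid(outer(lats, lons, function(la, lo) a + bLon * lo + bLat * la),
       origin, cs, name)
}

# Session-cached default synthetic worlds keyed by seed: environment stack,
# per-subarea surveys, extracted predictor tables restricted to the
# designed retained set.
.worldCache <- new.env(parent = emptyenv())
syntheticWorld <- function(seed, nTows = 600) {
  key <- sprintf("w%d_%d", seed, nTows)
  if (!is.null(.worldCache[[key]])) return(.worldCache[[key]])
  regimes <- list(warmProxyRegime(), coldProxyRegime())
  env <- generateEnvironment(regimes, seed = seed)
  areas <- list()
  for (i in seq_along(regimes)) {
    rg <- regimes[[i]]
    occ <- generateOccurrences(env$stack, rg,
                               surveyConfig(nTows = nTows,
                                            seed = seed * 100 + i),
                               mask = env$masks[[rg$subarea_name]])
    ext <- extractAtPoints(env$stack, occ$records)
    areas[[rg$subarea_name]] <- list(
      survey = occ, labels = occ$records$true_label,
      pred = ext[, designedRetainedSet()],
      predAll = ext[, gridNames(env$stack)])
  }
  w <- list(env = env, areas = areas)
  .worldCache[[key]] <- w
  w
}
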