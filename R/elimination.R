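# Iterative pairwise-correlation predictor elimination. At each step the
# remaining pair with the highest |R| is considered and one member removed
# by the first applicable rule of a preference ladder: metric (mean first,
# then range, then a per-variable min/max preference), then season (annual
# before seasonal, fall before summer), then stratum (surface before
# bottom), then a deterministic tie-break.

#' Pairwise Pearson correlations between stack layers
#'
#' @slot r symmetric matrix of Pearson R over jointly valid cells; NA where
#'   undefined (constant layer).
#' @slot n matrix of jointly-valid cell counts per pair.
#' @export
setClass("CorrelationMatrix", representation(r = "matrix", n = "matrix"))

setValidity("CorrelationMatrix", function(object) {
  if (!identical(dim(object@r), dim(object@n))) return("r/n shape mismatch")
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE)) return("|R| > 1")
  TRUE
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d predictors\n", nrow(object@r)))
  print(round(object@r, 3))
})

#' Compute the correlation matrix of a predictor stack
#'
#' Pearson correlation for every layer pair over the cells valid in both
#' layers (optionally restricted to a subarea mask). A constant layer has
#' undefined correlations; these are reported as NA with a warning and
#' treated as 0 when ranking pairs for elimination.
#'
#' @param stack a \code{\link{GridStack}} (>= 2 layers).
#' @param mask optional 1/NA \code{Grid}; only its valid cells are used
#'   (default: the full study area).
#' @return a \code{\link{CorrelationMatrix}}.
#' @export
correlationMatrix <- function(stack, mask = NULL) {
  nms <- gridNames(stack)
  p <- length(nms)
  if (p < 2L) stop("need at least two predictors")
  vals <- vapply(nms, function(nm) as.vector(stack[[nm]]@values),
                 numeric(prod(gridDim(stack))))
  if (!is.null(mask)) vals <- vals[!is.na(as.vector(mask@values)), , drop = FALSE]
  r <- matrix(NA_real_, p, p, dimnames = list(nms, nms))
  nmat <- matrix(0L, p, p, dimnames = list(nms, nms))
  warned <- FALSE
  for (a in seq_len(p)) {
    r[a, a] <- 1
    nmat[a, a] <- sum(!is.na(vals[, a]))
    for (b in seq_len(p)[-seq_len(a)]) {
      ok <- !is.na(vals[, a]) & !is.na(vals[, b])
      nab <- sum(ok)
      nmat[a, b] <- nmat[b, a] <- nab
      if (nab < 3L)
        stop(sprintf("fewer than 3 jointly valid cells for pair (%s, %s)",
                     nms[a], nms[b]))
      if (var(vals[ok, a]) == 0 || var(vals[ok, b]) == 0) {
        warned <- TRUE
      } else {
        r[a, b] <- r[b, a] <- cor(vals[ok, a], vals[ok, b])
      }
    }
  }
  if (warned)
    warning("constant layer(s): undefined correlations reported as NA and ",
            "ranked as 0")
  new("CorrelationMatrix", r = r, n = nmat)
}

#' Default elimination preferences
#'
#' The per-variable min/max preference used when a minimum and a maximum of
#' the same quantity are correlated: the metric most plausibly acting as a
#' tolerance limit is retained (minimum for bottom salinity — a lower
#' salinity tolerance; maximum for temperature and chlorophyll; maximum for
#' current and shear).
#'
#' @return list with element \code{minmax}: named character vector mapping
#'   base variable to the retained metric ("min" or "max").
#' @export
defaultEliminationPreferences <- function() {
  list(minmax = c(salinity = "min", temperature = "max", chl = "max",
                  current = "max", shear = "max"))
}

# decide which member of a correlated pair to eliminate; returns
# list(eliminated, rule)
.eliminationRule <- function(a, b, rAbs, remaining, preferences) {
  pa <- parsePredictorName(a); pb <- parsePredictorName(b)
  # (1) metric ladder: same quantity, different metrics
  if (pa$base == pb$base && pa$season == pb$season &&
      pa$stratum == pb$stratum && pa$metric != pb$metric &&
      pa$metric != "none" && pb$metric != "none") {
    for (victim in c("mean", "range")) {
      if (pa$metric == victim) return(list(eliminated = a, rule = "metric-ladder"))
      if (pb$metric == victim) return(list(eliminated = b, rule = "metric-ladder"))
    }
    pref <- unname(preferences$minmax[pa$base])
    if (length(pref) != 1L || is.na(pref))
      stop("min/max preference missing for variable: ", pa$base)
    if (pa$metric == pref) return(list(eliminated = b, rule = "min/max-table"))
    return(list(eliminated = a, rule = "min/max-table"))
  }
  # (2) season: annual eliminated over seasonal; fall over summer
  if (pa$season != "none" && pb$season != "none" && pa$season != pb$season) {
    if (pa$season == "annual") return(list(eliminated = a, rule = "season-annual"))
    if (pb$season == "annual") return(list(eliminated = b, rule = "season-annual"))
    if (pa$season == "fall") return(list(eliminated = a, rule = "season-fall"))
    if (pb$season == "fall") return(list(eliminated = b, rule = "season-fall"))
  }
  # (3) stratum: surface eliminated over bottom
  if (pa$stratum != pb$stratum) {
    if (pa$stratum == "surface") return(list(eliminated = a, rule = "stratum-surface"))
    if (pb$stratum == "surface") return(list(eliminated = b, rule = "stratum-surface"))
  }
  # (4) tie-break: larger mean |R| against the other remaining predictors;
  # final fallback lexicographic (later name eliminated)
  others <- setdiff(remaining, c(a, b))
  if (length(others)) {
    ra <- mean(rAbs[a, others]); rb <- mean(rAbs[b, others])
    if (ra > rb) return(list(eliminated = a, rule = "tiebreak"))
    if (rb > ra) return(list(eliminated = b, rule = "tiebreak"))
  }
  list(eliminated = if (a > b) a else b, rule = "tiebreak")
}

#' Iteratively eliminate correlated predictors
#'
#' Repeats: find the remaining pair with maximal |R|; stop if it does not
#' exceed the threshold; otherwise eliminate one member by the preference
#' ladder and record the step. Exact ties in "highest correlation" are
#' broken by first pair in row-major order of the matrix, making the trace
#' deterministic. After completion every retained pair satisfies
#' |R| <= threshold.
#'
#' @param corr a \code{\link{CorrelationMatrix}}.
#' @param threshold |R| above which a pair is "highly correlated"
#'   (default 0.5).
#' @param preferences see \code{\link{defaultEliminationPreferences}}.
#' @return an \code{\link{EliminationTrace}}.
#' @export
eliminate <- function(corr, threshold = 0.5,
                      preferences = defaultEliminationPreferences()) {
  rAbs <- abs(corr@r)
  rAbs[is.na(rAbs)] <- 0          # undefined pairs rank lowest
  nms <- rownames(rAbs)
  remaining <- nms
  steps <- list()
  repeat {
    sub <- rAbs[remaining, remaining, drop = FALSE]
    diag(sub) <- 0
    best <- max(sub)
    if (best <= threshold) break
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    a <- remaining[hit[1L, 1L]]; b <- remaining[hit[1L, 2L]]
    dec <- .eliminationRule(a, b, rAbs, remaining, preferences)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, var_a = a, var_b = b, abs_r = best,
      eliminated = dec$eliminated, rule = dec$rule,
      stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, dec$eliminated)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), var_a = character(), var_b = character(),
               abs_r = numeric(), eliminated = character(),
               rule = character(), stringsAsFactors = FALSE)
  new("EliminationTrace", steps = steps,
      retained = nms[nms %in% remaining], threshold = threshold)
}

#' Eliminate correlated predictors directly from a stack
#'
#' Convenience wrapper: computes the correlation matrix over the study area
#' (or a subarea mask) and runs \code{\link{eliminate}}. Correlations are
#' computed over the full study area by default — the standard procedure —
#' but a subarea mask can be supplied for per-area sensitivity runs, since
#' full-area elimination can remove predictors that are uncorrelated within
#' a particular subarea.
#'
#' @inheritParams correlationMatrix
#' @inheritParams eliminate
#' @return an \code{\link{EliminationTrace}}.
#' @export
eliminatePredictors <- function(stack, threshold = 0.5,
                                preferences = defaultEliminationPreferences(),
                                mask = NULL) {
  eliminate(correlationMatrix(stack, mask = mask), threshold = threshold,
            preferences = preferences)
}
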