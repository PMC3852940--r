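# Train-in-one-area / evaluate-in-another extrapolation experiments and the
# proxy-predictor ablation diagnostic. Within-area fit is measured by
# repeated cross-validation; cross-area fit by a single model trained on all
# training-area records and scored on the disjoint test area.

#' Transfer AUC: train in one area, score in another
#'
#' Fits a forest on ALL training-area records (no cross-validation: the test
#' data are disjoint) and computes the AUC of its predictions against the
#' test area's labels.
#'
#' @param trainOcc,trainPred training-area \code{\link{OccurrenceSet}} (or
#'   labels) and predictor table.
#' @param testOcc,testPred test-area occurrences and predictor table; the
#'   predictor sets must be identical.
#' @param seed RNG seed for the forest.
#' @param ntree trees per forest.
#' @return AUC in [0, 1].
#' @export
transferAUC <- function(trainOcc, trainPred, testOcc, testPred, seed = 1L,
                        ntree = 500L) {
  asym <- union(setdiff(colnames(trainPred), colnames(testPred)),
                setdiff(colnames(testPred), colnames(trainPred)))
  if (length(asym))
    stop("predictor sets differ between areas: ",
         paste(asym, collapse = ", "))
  model <- fitOccurrenceModel(trainOcc, trainPred, seed = seed,
                              ntree = ntree)
  sc <- predictPresence(model, testPred)
  y <- if (is(testOcc, "OccurrenceSet")) occurrenceRecords(testOcc)$label
       else testOcc
  aucMW(sc, y)
}

#' Proxy-predictor ablation experiment
#'
#' Computes the transfer AUC twice with the same seed: with the full
#' predictor set, and with a set of suspected proxy predictors (typically
#' depth and slope) removed from the training data. When proxies carry
#' regime-specific relationships, the ablated model generalises better
#' across regimes.
#'
#' @inheritParams transferAUC
#' @param drop character vector of predictor names to remove (must be a
#'   subset of the predictors; dropping all of them is an error).
#' @return list with \code{full} and \code{ablated} AUCs, and \code{drop}.
#' @export
proxyAblation <- function(trainOcc, trainPred, testOcc, testPred,
                          drop = c("depth", "slope"), seed = 1L,
                          ntree = 500L) {
  miss <- setdiff(drop, colnames(trainPred))
  if (length(miss))
    stop("drop set contains unknown predictor(s): ",
         paste(miss, collapse = ", "))
  keep <- setdiff(colnames(trainPred), drop)
  if (length(keep) == 0L) stop("cannot drop all predictors")
  full <- transferAUC(trainOcc, trainPred, testOcc, testPred,
                      seed = seed, ntree = ntree)
  ablated <- transferAUC(trainOcc, trainPred[, keep, drop = FALSE],
                         testOcc, testPred[, keep, drop = FALSE],
                         seed = seed, ntree = ntree)
  list(full = full, ablated = ablated, drop = drop)
}

#' Full transfer matrix over a set of areas
#'
#' Fills a train-area x test-area AUC matrix for one response: diagonal
#' cells are within-area repeated-CV means; off-diagonal cells are transfer
#' AUCs from a single all-data training fit. The matrix is not symmetric in
#' general. An area failing its preconditions (e.g. a single-class response)
#' marks its cells NA and the run continues.
#'
#' @param areas named list; each element a list with \code{occ} (an
#'   \code{\link{OccurrenceSet}} or labels) and \code{pred} (predictor
#'   table).
#' @param seed RNG seed.
#' @param k,repeats within-area cross-validation settings.
#' @param ntree trees per forest.
#' @return matrix of AUCs, rows = training area, cols = test area.
#' @export
transferMatrix <- function(areas, seed = 1L, k = 10L, repeats = 10L,
                           ntree = 500L) {
  if (length(areas) < 2L) stop("need at least two areas")
  nms <- names(areas)
  m <- matrix(NA_real_, length(areas), length(areas),
              dimnames = list(train = nms, test = nms))
  for (a in nms) for (b in nms) {
    m[a, b] <- tryCatch({
      if (a == b)
        cvAUC(repeatedCV(areas[[a]]$occ, areas[[a]]$pred, k = k,
                         repeats = repeats, seed = seed, ntree = ntree))
      else
        transferAUC(areas[[a]]$occ, areas[[a]]$pred,
                    areas[[b]]$occ, areas[[b]]$pred,
                    seed = seed, ntree = ntree)
    }, error = function(e) {
      warning(sprintf("transfer cell (%s -> %s) unavailable: %s",
                      a, b, conditionMessage(e)))
      NA_real_
    })
  }
  m
}
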