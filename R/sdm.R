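# Random-forest presence/absence modeling and its evaluation suite:
# Mann-Whitney AUC, repeated stratified cross-validation, per-split
# permutation importance on the AUC scale, partial dependence at mean
# observed covariate values, and raster prediction.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen presence is scored above a
#' randomly chosen absence, with ties counted one half — computed via the
#' midrank identity, equivalent to exhaustive pairwise counting.
#'
#' @param scores numeric prediction scores (higher = more presence-like).
#' @param labels presence/absence labels: a factor with levels
#'   absence/presence, a logical, or a 0/1 vector (1 = presence).
#' @return AUC in [0, 1].
#' @export
aucMW <- function(scores, labels) {
  pos <- .asPresence(labels)
  nP <- sum(pos); nA <- sum(!pos)
  if (nP == 0L || nA == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nA)
}

.asPresence <- function(labels) {
  if (is.factor(labels)) labels == "presence"
  else if (is.logical(labels)) labels
  else labels == 1
}

.asLabelFactor <- function(labels) {
  factor(ifelse(.asPresence(labels), "presence", "absence"),
         levels = c("absence", "presence"))
}

#' Fit a random-forest occurrence model
#'
#' Grows a classification forest with the standard defaults of the
#' reference implementation: 500 trees, floor(sqrt(p)) candidate predictors
#' per split, unpruned trees, bootstrap samples the size of the training
#' set, no class weighting. Presence probability is the fraction of tree
#' votes for presence.
#'
#' @param occurrences an \code{\link{OccurrenceSet}}, or any label vector
#'   accepted by \code{\link{aucMW}}.
#' @param predictors data.frame of predictor values, rows aligned with the
#'   occurrence records; must be complete (exclude flagged rows upstream).
#' @param seed RNG seed for the forest.
#' @param ntree number of trees (method default 500; smaller values are
#'   useful for large repeated-CV experiments).
#' @param subarea label stored on the bundle.
#' @return a \code{\link{ModelBundle}}.
#' @export
fitOccurrenceModel <- function(occurrences, predictors, seed = 1L,
                               ntree = 500L, subarea = "unknown") {
  y <- if (is(occurrences, "OccurrenceSet")) {
    subarea <- occurrences@subarea
    occurrenceRecords(occurrences)$label
  } else .asLabelFactor(occurrences)
  y <- .asLabelFactor(y)
  if (ncol(predictors) == 0L) stop("no predictors supplied")
  if (anyNA(predictors))
    stop("predictor table contains missing values; exclude flagged rows")
  if (length(unique(y)) < 2L || any(table(y) == 0L))
    stop("degenerate response: both classes are required")
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = as.data.frame(predictors), y = y, ntree = as.integer(ntree))
  new("ModelBundle", forest = forest, predictors = colnames(predictors),
      subarea = subarea, classPrior = as.numeric(table(y) / length(y)),
      seed = as.integer(seed))
}

#' Predict presence probability at points
#'
#' @param model a \code{\link{ModelBundle}}.
#' @param newdata data.frame containing all model predictors.
#' @return presence probabilities (vote fractions) in [0, 1].
#' @export
predictPresence <- function(model, newdata) {
  miss <- setdiff(model@predictors, colnames(newdata))
  if (length(miss))
    stop("missing predictor(s): ", paste(miss, collapse = ", "))
  as.numeric(predict(model@forest,
                     newdata[, model@predictors, drop = FALSE],
                     type = "prob")[, "presence"])
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds, so every fold tests on both classes
.stratifiedFolds <- function(pos, k) {
  n <- length(pos)
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    if (length(idx) < k)
      stop(sprintf(
        "class with %d records cannot be stratified into %d folds; use smaller k",
        length(idx), k))
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validated AUC
#'
#' For each of \code{repeats} random stratified partitions into \code{k}
#' folds, fits a forest on k-1 folds and scores the held-out fold; the
#' headline statistic is the mean of the per-fold AUCs ("average" scoring)
#' or the AUC of all out-of-fold scores pooled ("pooled").
#'
#' @inheritParams fitOccurrenceModel
#' @param k folds (default 10). @param repeats repeats (default 10).
#' @param scoring "average" (per-fold AUCs averaged) or "pooled".
#' @param keepModels retain per-split fitted models and test indices (needed
#'   by \code{\link{permutationImportance}}).
#' @return a \code{\link{CVResult}}.
#' @export
repeatedCV <- function(occurrences, predictors, k = 10L, repeats = 10L,
                       seed = 1L, ntree = 500L,
                       scoring = c("average", "pooled"),
                       keepModels = FALSE) {
  scoring <- match.arg(scoring)
  y <- if (is(occurrences, "OccurrenceSet"))
    occurrenceRecords(occurrences)$label else .asLabelFactor(occurrences)
  pos <- .asPresence(y)
  yF <- .asLabelFactor(y)
  predictors <- as.data.frame(predictors)
  if (anyNA(predictors)) stop("predictor table contains missing values")
  set.seed(as.integer(seed))
  # stratified folds keep both classes in every test set; pooled scoring can
  # fall back to plain folds (e.g. leave-one-out) since only the pooled
  # scores need both classes
  plainFolds <- k > min(sum(pos), sum(!pos))
  if (plainFolds && scoring != "pooled")
    .stratifiedFolds(pos, k)   # signals the informative error
  rows <- list(); folds <- list(); state <- list()
  pooledAll <- numeric(0)
  pooledLab <- logical(0)
  for (r in seq_len(repeats)) {
    fold <- if (plainFolds) sample(rep_len(seq_len(k), length(y)))
            else .stratifiedFolds(pos, k)
    folds[[r]] <- fold
    for (f in seq_len(k)) {
      test <- which(fold == f); train <- which(fold != f)
      forest <- randomForest::randomForest(
        x = predictors[train, , drop = FALSE], y = yF[train],
        ntree = as.integer(ntree))
      sc <- as.numeric(predict(forest, predictors[test, , drop = FALSE],
                               type = "prob")[, "presence"])
      foldAUC <- if (length(unique(pos[test])) == 2L) aucMW(sc, pos[test])
                 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, auc = foldAUC)
      pooledAll <- c(pooledAll, sc); pooledLab <- c(pooledLab, pos[test])
      if (keepModels)
        state[[length(state) + 1L]] <- list(rep = r, fold = f,
                                            forest = forest, test = test,
                                            scores = sc)
    }
  }
  aucTab <- do.call(rbind, rows)
  meanAUC <- if (scoring == "average") mean(aucTab$auc, na.rm = TRUE)
             else aucMW(pooledAll, pooledLab)
  new("CVResult", auc = aucTab, meanAUC = meanAUC, k = as.integer(k),
      repeats = as.integer(repeats), scoring = scoring,
      seed = as.integer(seed), folds = folds, state = state)
}

#' Permutation importance on the AUC scale, per cross-validation split
#'
#' For every retained cross-validation split and every requested predictor,
#' the predictor's TEST-set values are randomly shuffled \code{nPerm} times
#' and the held-out AUC recomputed; importance is the mean reduction
#' (unpermuted AUC minus permuted AUC) over splits x permutations, so
#' results do not hinge on a specific split or permutation. A predictor
#' constant over a test set contributes exactly zero for that split.
#'
#' @param cv a \code{\link{CVResult}} from \code{\link{repeatedCV}} with
#'   \code{keepModels = TRUE}.
#' @param predictors the same predictor table the CV was run on.
#' @param labels the same labels the CV was run on.
#' @param predictorNames predictors to assess (default: all in the model).
#' @param nPerm permutations per split (default 10).
#' @param seed RNG seed for the shuffles.
#' @return data.frame with columns \code{predictor}, \code{importance}
#'   (mean AUC reduction), \code{sd} (over splits x permutations).
#' @export
permutationImportance <- function(cv, predictors, labels,
                                  predictorNames = NULL, nPerm = 10L,
                                  seed = 1L) {
  if (length(cv@state) == 0L)
    stop("CVResult has no retained models; rerun repeatedCV with keepModels = TRUE")
  predictors <- as.data.frame(predictors)
  pos <- .asPresence(if (is(labels, "OccurrenceSet"))
    occurrenceRecords(labels)$label else labels)
  if (is.null(predictorNames)) predictorNames <- colnames(predictors)
  miss <- setdiff(predictorNames, colnames(predictors))
  if (length(miss))
    stop("predictor(s) not in model: ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  out <- lapply(predictorNames, function(v) {
    red <- numeric(0)
    for (s in cv@state) {
      test <- s$test
      base <- aucMW(s$scores, pos[test])
      td <- predictors[test, , drop = FALSE]
      for (p in seq_len(nPerm)) {
        tp <- td
        tp[[v]] <- tp[[v]][sample.int(nrow(tp))]
        sc <- as.numeric(predict(s$forest, tp, type = "prob")[, "presence"])
        red <- c(red, base - aucMW(sc, pos[test]))
      }
    }
    data.frame(predictor = v, importance = mean(red), sd = sd(red),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partial dependence of predicted presence probability on one predictor
#'
#' Varies a single predictor over a grid spanning its observed range while
#' holding every other predictor at its mean observed value, and predicts
#' one synthetic point per grid value. This is the single-point variant —
#' the response of the model at the covariate means — not the
#' dataset-averaged partial dependence; set \code{average = TRUE} for the
#' averaged variant, which replaces the predictor column in the full
#' training table and averages the predictions.
#'
#' @param model a \code{\link{ModelBundle}}.
#' @param predictorName predictor to vary.
#' @param trainingTable training predictor table (supplies means and range).
#' @param nGrid grid size (default 100).
#' @param average use the dataset-averaged variant.
#' @return data.frame with columns \code{value}, \code{probability}; the
#'   predictor name is attached as attribute "predictor".
#' @export
partialDependence <- function(model, predictorName, trainingTable,
                              nGrid = 100L, average = FALSE) {
  if (!(predictorName %in% model@predictors))
    stop("predictor not in model: ", predictorName)
  trainingTable <- as.data.frame(trainingTable)
  v <- trainingTable[[predictorName]]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("zero-variance predictor '", predictorName,
            "': returning a single-point curve")
    grid <- rng[1]
  } else grid <- seq(rng[1], rng[2], length.out = nGrid)
  if (average) {
    prob <- vapply(grid, function(g) {
      td <- trainingTable
      td[[predictorName]] <- g
      mean(predictPresence(model, td))
    }, numeric(1))
  } else {
    base <- as.data.frame(lapply(trainingTable[model@predictors], mean))
    nd <- base[rep(1L, length(grid)), , drop = FALSE]
    nd[[predictorName]] <- grid
    prob <- predictPresence(model, nd)
  }
  out <- data.frame(value = grid, probability = prob)
  attr(out, "predictor") <- predictorName
  out
}

#' Locate the steepest ascent of a partial-dependence curve
#'
#' Smooths the curve with a short running mean and returns the predictor
#' value at the midpoint of the segment with the largest positive slope —
#' the model-implied location of a lower tolerance threshold.
#'
#' @param pd a curve from \code{\link{partialDependence}}.
#' @param window running-mean window (grid points, odd).
#' @return predictor value of the steepest ascent.
#' @export
steepestAscent <- function(pd, window = 7L) {
  p <- pd$probability
  if (length(p) < 3L) return(pd$value[1L])
  k <- rep(1 / window, window)
  sm <- as.numeric(stats::filter(p, k, sides = 2))
  na <- is.na(sm)
  sm[na] <- p[na]
  slope <- diff(sm)
  i <- which.max(slope)
  (pd$value[i] + pd$value[i + 1L]) / 2
}

#' Predict a presence-probability raster
#'
#' Applies the model to every cell of the stack; a cell is nodata in the
#' output wherever any predictor is nodata. Predicting at a cell center
#' point gives exactly the raster value of that cell.
#'
#' @param model a \code{\link{ModelBundle}}.
#' @param stack a \code{\link{GridStack}} supplying every model predictor.
#' @return a \code{Grid} of presence probability in [0, 1].
#' @export
predictRaster <- function(model, stack) {
  miss <- setdiff(model@predictors, gridNames(stack))
  if (length(miss))
    stop("missing predictor layer(s): ", paste(miss, collapse = ", "))
  d <- gridDim(stack)
  tab <- as.data.frame(lapply(model@predictors,
                              function(nm) as.vector(stack[[nm]]@values)))
  colnames(tab) <- model@predictors
  ok <- !apply(is.na(tab), 1L, any)
  out <- rep(NA_real_, prod(d))
  if (any(ok))
    out[ok] <- predictPresence(model, tab[ok, , drop = FALSE])
  ref <- stack[[1L]]
  Grid(matrix(out, d[1], d[2]), ref@origin, ref@cellSize,
       "presence_probability", "")
}
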