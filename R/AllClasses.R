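#' @import methods
#' @importFrom stats cor predict quantile rbinom rexp rlnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
#' @importFrom tools md5sum
NULL

#' Georeferenced single-layer grid
#'
#' A lightweight raster: a numeric matrix in geographic (WGS84) coordinates
#' with cell-center registration. Row 1 is the northernmost row, column 1 the
#' westernmost column. Missing data are encoded as \code{NA} in \code{values}.
#'
#' @slot values numeric matrix; rows run north to south, columns west to east.
#' @slot origin numeric(2): lon/lat of the center of the north-west cell, in
#'   decimal degrees (longitude in -180..180).
#' @slot cellSize numeric(1): cell size in decimal degrees (square cells).
#' @slot name character(1): predictor label, unique within a stack.
#' @slot units character(1): free-text units (e.g. "m", "psu", "degC").
#'
#' @examples
#' g <- Grid(matrix(1:6, 2, 3), origin = c(-60, 47), cellSize = 0.017,
#'           name = "depth", units = "m")
#' gridDim(g)
#' @export
setClass("Grid",
  representation(values = "matrix", origin = "numeric",
                 cellSize = "numeric", name = "character",
                 units = "character"),
  prototype(units = ""))

setValidity("Grid", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (length(object@origin) != 2L || anyNA(object@origin))
    msg <- c(msg, "origin must be numeric(2) lon/lat")
  if (length(object@cellSize) != 1L || is.na(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Named, co-registered set of grids
#'
#' The predictor space: an ordered, named list of \code{\link{Grid}} objects
#' sharing origin, cell size and shape exactly.
#'
#' @slot grids named list of \code{Grid} objects.
#' @export
setClass("GridStack", representation(grids = "list"))

setValidity("GridStack", function(object) {
  gs <- object@grids
  if (length(gs) == 0L) return("stack must contain at least one grid")
  if (!all(vapply(gs, is, logical(1), "Grid")))
    return("all elements must be Grid objects")
  nms <- unname(vapply(gs, function(g) g@name, character(1)))
  if (!identical(names(gs), nms))
    return("list names must equal the grids' name slots")
  if (anyDuplicated(nms)) return("grid names must be unique")
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!identical(dim(g@values), dim(ref@values)) ||
        !identical(g@origin, ref@origin) ||
        !identical(g@cellSize, ref@cellSize))
      return(sprintf("grid '%s' is not co-registered with '%s'",
                     g@name, ref@name))
  }
  TRUE
})

#' Labeled presence/absence points for one response
#'
#' @slot response character(1): "sponge_ground", a genus, or a species label.
#' @slot subarea character(1): subarea tag the records belong to.
#' @slot records data.frame with columns \code{lon}, \code{lat} and
#'   \code{label} (factor with levels \code{absence}, \code{presence}).
#' @export
setClass("OccurrenceSet",
  representation(response = "character", subarea = "character",
                 records = "data.frame"))

setValidity("OccurrenceSet", function(object) {
  rec <- object@records
  need <- c("lon", "lat", "label")
  if (!all(need %in% names(rec)))
    return("records must have columns lon, lat, label")
  if (!is.factor(rec$label) ||
      !identical(levels(rec$label), c("absence", "presence")))
    return("label must be a factor with levels absence, presence")
  TRUE
})

#' Audit trace of correlation-based predictor elimination
#'
#' @slot steps data.frame with one row per eliminated predictor: columns
#'   \code{step}, \code{var_a}, \code{var_b}, \code{abs_r},
#'   \code{eliminated}, \code{rule}.
#' @slot retained character: predictors surviving elimination, input order.
#' @slot threshold numeric(1): the |R| cutoff used.
#' @export
setClass("EliminationTrace",
  representation(steps = "data.frame", retained = "character",
                 threshold = "numeric"))

setValidity("EliminationTrace", function(object) {
  if (any(object@steps$eliminated %in% object@retained))
    return("eliminated predictors must not reappear in the retained set")
  TRUE
})

#' Fitted occurrence model bundle
#'
#' Wraps a fitted random forest together with the metadata needed to apply it
#' to new points or rasters: predictor order, training subarea, class prior
#' and the seed that grew it.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot predictors character: predictor names in training order.
#' @slot subarea character(1): training subarea label.
#' @slot classPrior numeric(2): training fractions of absence/presence.
#' @slot seed integer(1): RNG seed used for fitting.
#' @export
setClass("ModelBundle",
  representation(forest = "ANY", predictors = "character",
                 subarea = "character", classPrior = "numeric",
                 seed = "integer"))

setValidity("ModelBundle", function(object) {
  if (length(object@predictors) == 0L) return("predictor list is empty")
  if (anyDuplicated(object@predictors)) return("duplicate predictor names")
  TRUE
})

#' Repeated cross-validation result
#'
#' @slot auc data.frame with columns \code{rep}, \code{fold}, \code{auc}.
#' @slot meanAUC numeric(1): mean of the per-fold AUCs (or the pooled-score
#'   AUC when pooled scoring was requested).
#' @slot k integer(1): folds. @slot repeats integer(1): repeats.
#' @slot scoring character(1): "average" or "pooled".
#' @slot seed integer(1).
#' @slot folds list of per-repeat fold assignments.
#' @slot state list: per-split fitted models, test indices and test scores,
#'   retained only when \code{keepModels = TRUE} (needed for permutation
#'   importance).
#' @export
setClass("CVResult",
  representation(auc = "data.frame", meanAUC = "numeric", k = "integer",
                 repeats = "integer", scoring = "character",
                 seed = "integer", folds = "list", state = "list"))

setValidity("CVResult", function(object) {
  if (nrow(object@auc) != object@k * object@repeats)
    return("auc table must have k * repeats rows")
  ok <- object@auc$auc
  if (any(ok < 0 | ok > 1, na.rm = TRUE)) return("AUC outside [0,1]")
  TRUE
})

setMethod("show", "Grid", function(object) {
  d <- dim(object@values)
  cat(sprintf("Grid '%s' [%s]: %d x %d cells, %.4g deg, NW center (%.4f, %.4f), %d nodata\n",
              object@name, object@units, d[1], d[2], object@cellSize,
              object@origin[1], object@origin[2], sum(is.na(object@values))))
})

setMethod("show", "GridStack", function(object) {
  cat(sprintf("GridStack: %d layers, %d x %d cells\n", length(object@grids),
              nrow(object@grids[[1]]@values), ncol(object@grids[[1]]@values)))
  cat(" ", paste(names(object@grids), collapse = ", "), "\n")
})

setMethod("show", "OccurrenceSet", function(object) {
  tab <- table(object@records$label)
  cat(sprintf("OccurrenceSet '%s' (subarea %s): %d presences, %d absences\n",
              object@response, object@subarea,
              tab[["presence"]], tab[["absence"]]))
})

setMethod("show", "EliminationTrace", function(object) {
  cat(sprintf("EliminationTrace: %d eliminated at |R| > %.2f, %d retained\n",
              nrow(object@steps), object@threshold, length(object@retained)))
  if (nrow(object@steps)) print(object@steps, row.names = FALSE)
  cat("retained:", paste(object@retained, collapse = ", "), "\n")
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle (subarea %s): %d predictors, %d trees, seed %d\n",
              object@subarea, length(object@predictors),
              object@forest$ntree, object@seed))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold x %d repeats (%s scoring), mean AUC %.3f\n",
              object@k, object@repeats, object@scoring, object@meanAUC))
})
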