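#' @rdname Grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname Grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname Grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname Grid-accessors
#' @export
setGeneric("gridName", function(x) standardGeneric("gridName"))
#' @rdname Grid-accessors
#' @export
setGeneric("gridUnits", function(x) standardGeneric("gridUnits"))
#' @rdname Grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname GridStack-accessors
#' @export
setGeneric("gridNames", function(x) standardGeneric("gridNames"))
#' @rdname GridStack-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname OccurrenceSet-accessors
#' @export
setGeneric("occurrenceRecords", function(x) standardGeneric("occurrenceRecords"))
#' @rdname OccurrenceSet-accessors
#' @export
setGeneric("responseLabel", function(x) standardGeneric("responseLabel"))
#' @rdname EliminationTrace-accessors
#' @export
setGeneric("retainedPredictors", function(x) standardGeneric("retainedPredictors"))
#' @rdname EliminationTrace-accessors
#' @export
setGeneric("eliminationSteps", function(x) standardGeneric("eliminationSteps"))
#' @rdname CVResult-accessors
#' @export
setGeneric("cvAUC", function(x) standardGeneric("cvAUC"))
#' @rdname CVResult-accessors
#' @export
setGeneric("foldAUCs", function(x) standardGeneric("foldAUCs"))

#' Accessors for Grid objects
#'
#' @param x a \code{\link{Grid}}.
#' @return \code{gridValues}: the value matrix (rows north to south);
#'   \code{cellSize}: cell size in degrees; \code{gridOrigin}: lon/lat of the
#'   north-west cell center; \code{gridDim}: c(rows, cols);
#'   \code{gridName}/\code{gridUnits}: labels.
#' @name Grid-accessors
NULL

#' @rdname Grid-accessors
setMethod("gridValues", "Grid", function(x) x@values)
#' @rdname Grid-accessors
setMethod("cellSize", "Grid", function(x) x@cellSize)
#' @rdname Grid-accessors
setMethod("gridOrigin", "Grid", function(x) x@origin)
#' @rdname Grid-accessors
setMethod("gridName", "Grid", function(x) x@name)
#' @rdname Grid-accessors
setMethod("gridUnits", "Grid", function(x) x@units)
#' @rdname Grid-accessors
setMethod("gridDim", "Grid", function(x) dim(x@values))

#' Accessors for GridStack objects
#'
#' @param x a \code{\link{GridStack}}.
#' @name GridStack-accessors
NULL

#' @rdname GridStack-accessors
setMethod("gridNames", "GridStack", function(x) names(x@grids))
#' @rdname GridStack-accessors
setMethod("nLayers", "GridStack", function(x) length(x@grids))
#' @rdname GridStack-accessors
setMethod("cellSize", "GridStack", function(x) x@grids[[1L]]@cellSize)
#' @rdname GridStack-accessors
setMethod("gridOrigin", "GridStack", function(x) x@grids[[1L]]@origin)
#' @rdname GridStack-accessors
setMethod("gridDim", "GridStack", function(x) dim(x@grids[[1L]]@values))

#' @rdname GridStack-accessors
#' @param i layer name or index.
#' @param j,... unused.
#' @param exact unused (S4 signature requirement).
#' @export
setMethod("[[", "GridStack", function(x, i, j, ...) x@grids[[i]])

#' Accessors for OccurrenceSet objects
#'
#' @param x an \code{\link{OccurrenceSet}}.
#' @name OccurrenceSet-accessors
NULL

#' @rdname OccurrenceSet-accessors
setMethod("occurrenceRecords", "OccurrenceSet", function(x) x@records)
#' @rdname OccurrenceSet-accessors
setMethod("responseLabel", "OccurrenceSet", function(x) x@response)

#' Accessors for EliminationTrace objects
#'
#' @param x an \code{\link{EliminationTrace}}.
#' @name EliminationTrace-accessors
NULL

#' @rdname EliminationTrace-accessors
setMethod("retainedPredictors", "EliminationTrace", function(x) x@retained)
#' @rdname EliminationTrace-accessors
setMethod("eliminationSteps", "EliminationTrace", function(x) x@steps)

#' Accessors for CVResult objects
#'
#' @param x a \code{\link{CVResult}}.
#' @return \code{cvAUC}: the headline mean AUC; \code{foldAUCs}: the
#'   per-(repeat, fold) AUC table.
#' @name CVResult-accessors
NULL

#' @rdname CVResult-accessors
setMethod("cvAUC", "CVResult", function(x) x@meanAUC)
#' @rdname CVResult-accessors
setMethod("foldAUCs", "CVResult", function(x) x@auc)
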