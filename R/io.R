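# Plain-text IO: Esri ASCII grids, YAML stack manifests, CSV records and
# thresholds, elimination-trace export. All formats are text so that runs
# are diffable and portable.

#' Write a Grid as an Esri ASCII grid (.asc)
#'
#' Cell-center registration is converted to the format's lower-left corner
#' convention; values are written at full double precision so read/write
#' round-trips are exact.
#'
#' @param grid a \code{\link{Grid}}.
#' @param path output file path.
#' @param nodata value used to encode NA.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  d <- dim(v)
  cs <- grid@cellSize
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.17g", grid@origin[1] - cs / 2),
           sprintf("yllcorner %.17g", grid@origin[2] - (d[1] - 1) * cs - cs / 2),
           sprintf("cellsize %.17g", cs),
           sprintf("NODATA_value %.17g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
}

#' Read an Esri ASCII grid (.asc)
#'
#' @param path file path.
#' @param name predictor label for the resulting grid (default: file stem).
#' @param units units label.
#' @return a \code{\link{Grid}}.
#' @export
readAsciiGrid <- function(path, name = sub("\\.asc$", "", basename(path)),
                          units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  cs <- hdr$cellsize
  origin <- c(hdr$xllcorner + cs / 2, hdr$yllcorner + cs / 2 + (nr - 1) * cs)
  Grid(v, origin, cs, name, units)
}

#' Write a GridStack as ASCII grids plus a YAML manifest
#'
#' @param stack a \code{\link{GridStack}}.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within \code{dir}.
#' @return the manifest path, invisibly.
#' @export
writeStack <- function(stack, dir, manifest = "stack.yml") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (nm in gridNames(stack)) {
    f <- paste0(nm, ".asc")
    writeAsciiGrid(stack[[nm]], file.path(dir, f))
    entries[[nm]] <- list(file = f, units = gridUnits(stack[[nm]]))
  }
  path <- file.path(dir, manifest)
  yaml::write_yaml(list(layers = entries), path)
  invisible(path)
}

#' Read a GridStack from a YAML manifest
#'
#' @param manifestPath path to a manifest written by \code{\link{writeStack}}.
#' @return a \code{\link{GridStack}}.
#' @export
readStack <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  dir <- dirname(manifestPath)
  gs <- lapply(names(man$layers), function(nm) {
    e <- man$layers[[nm]]
    readAsciiGrid(file.path(dir, e$file), name = nm,
                  units = if (is.null(e$units)) "" else e$units)
  })
  GridStack(gs)
}

#' Read gear/subarea presence thresholds from CSV
#'
#' Expected columns: \code{subarea}, \code{gear}, \code{threshold_kg}
#' (kg sponge per standard tow).
#'
#' @param path CSV file path.
#' @return data.frame of thresholds.
#' @export
readGearThresholds <- function(path) {
  th <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subarea", "gear", "threshold_kg")
  if (!all(need %in% names(th)))
    stop("threshold table must have columns subarea, gear, threshold_kg")
  if (any(th$threshold_kg <= 0)) stop("thresholds must be positive")
  th
}

#' Gear- and subarea-specific sponge-ground thresholds for the NW Atlantic
#'
#' The published kernel-density-derived local thresholds (kg sponge per
#' standard tow) separating sponge grounds from lower-density sponge
#' presence, by survey gear and subarea (FC, NL, HS, BB).
#'
#' @return data.frame with columns subarea, gear, threshold_kg.
#' @export
defaultGearThresholds <- function() {
  readGearThresholds(system.file("extdata", "gear_thresholds.csv",
                                 package = "spongeSDM", mustWork = TRUE))
}

#' Read trawl-survey records from CSV
#'
#' Expected columns: \code{tow_id}, \code{lon}, \code{lat}, \code{gear},
#' \code{sponge_weight_kg}; optional \code{subarea}, \code{taxon_ids}
#' (semicolon-separated), \code{total_sponge_present} (logical).
#'
#' @param path CSV file path.
#' @return data.frame of trawl records.
#' @export
readTrawlRecords <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tow_id", "lon", "lat", "gear", "sponge_weight_kg")
  if (!all(need %in% names(rec)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(rec$sponge_weight_kg < 0)) stop("sponge weights must be >= 0")
  if (is.null(rec$total_sponge_present))
    rec$total_sponge_present <- rec$sponge_weight_kg > 0
  rec
}

#' Write an occurrence set to CSV
#'
#' @param occ an \code{\link{OccurrenceSet}}.
#' @param path output CSV path.
#' @export
writeOccurrences <- function(occ, path) {
  df <- occurrenceRecords(occ)
  df$response <- responseLabel(occ)
  df$subarea <- occ@subarea
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an elimination trace
#'
#' @param trace an \code{\link{EliminationTrace}}.
#' @param csvPath optional path for the step table (CSV).
#' @param jsonPath optional path for the full trace (JSON).
#' @param retainedPath optional path for a plain-text retained-set manifest
#'   (one predictor name per line), consumable by the modeling stage.
#' @export
writeEliminationTrace <- function(trace, csvPath = NULL, jsonPath = NULL,
                                  retainedPath = NULL) {
  if (!is.null(csvPath))
    write.csv(eliminationSteps(trace), csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(threshold = trace@threshold,
           steps = eliminationSteps(trace),
           retained = retainedPredictors(trace)),
      jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(retainedPath))
    writeLines(retainedPredictors(trace), retainedPath)
  invisible(NULL)
}

#' Decompose a predictor name into its descriptive parts
#'
#' Predictor names follow the convention
#' \code{<variable>[_<season|stratum>][_<metric>]}: \code{depth} and
#' \code{slope} are bare; chlorophyll carries a season
#' (\code{annual}/\code{summer}/\code{fall}); physical ocean variables carry
#' a stratum (\code{surface}/\code{bottom}); the metric is one of
#' \code{min}/\code{mean}/\code{max}/\code{range}. Names outside the
#' convention (e.g. appended noise predictors) are treated as opaque base
#' variables with no metric, season or stratum.
#'
#' @param name predictor name string.
#' @return list with elements \code{base}, \code{metric}, \code{season},
#'   \code{stratum} ("none" where not applicable).
#' @export
parsePredictorName <- function(name) {
  metrics <- c("min", "mean", "max", "range")
  seasons <- c("annual", "summer", "fall")
  strata <- c("surface", "bottom")
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  out <- list(base = name, metric = "none", season = "none", stratum = "none")
  if (length(parts) >= 2L && parts[length(parts)] %in% metrics) {
    out$metric <- parts[length(parts)]
    parts <- parts[-length(parts)]
  }
  if (length(parts) >= 2L && parts[length(parts)] %in% seasons) {
    out$season <- parts[length(parts)]
    parts <- parts[-length(parts)]
  } else if (length(parts) >= 2L && parts[length(parts)] %in% strata) {
    out$stratum <- parts[length(parts)]
    parts <- parts[-length(parts)]
  }
  out$base <- paste(parts, collapse = "_")
  out
}
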