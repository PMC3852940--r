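# Converting trawl-catch records into presence/absence occurrence sets:
# gear/subarea threshold classification for sponge grounds, the
# strict-absence rule for taxa, and subarea assignment.

#' Classify trawl records into sponge-ground presence/absence
#'
#' Applies the gear- and subarea-specific wet-weight threshold: a record is
#' a sponge-ground presence iff its catch is strictly above the threshold
#' for its (subarea, gear) pair; all other records are absences ("above the
#' threshold" read as a strict inequality, so a catch exactly at the
#' threshold is an absence). Every input record receives exactly one label.
#'
#' @param records data.frame of trawl records with columns \code{lon},
#'   \code{lat}, \code{gear}, \code{subarea}, \code{sponge_weight_kg}.
#' @param thresholds data.frame with columns \code{subarea}, \code{gear},
#'   \code{threshold_kg} (see \code{\link{defaultGearThresholds}}).
#' @param subarea label stored on the resulting set (default: the single
#'   subarea present in \code{records}).
#' @return an \code{\link{OccurrenceSet}} with response "sponge_ground".
#' @export
classifySpongeGrounds <- function(records, thresholds,
                                  subarea = unique(records$subarea)) {
  key <- paste(records$subarea, records$gear, sep = "\r")
  tkey <- paste(thresholds$subarea, thresholds$gear, sep = "\r")
  hit <- match(key, tkey)
  if (anyNA(hit)) {
    miss <- unique(paste0("(", records$subarea, ", ", records$gear, ")")[
      is.na(hit)])
    stop("no threshold for gear/subarea pair(s): ",
         paste(miss, collapse = "; "))
  }
  thr <- thresholds$threshold_kg[hit]
  lab <- factor(ifelse(records$sponge_weight_kg > thr, "presence", "absence"),
                levels = c("absence", "presence"))
  new("OccurrenceSet", response = "sponge_ground",
      subarea = paste(subarea, collapse = "+"),
      records = data.frame(lon = records$lon, lat = records$lat,
                           label = lab))
}

#' Build taxon-level presence/absence occurrences
#'
#' Presence where the taxon was identified in the catch; absence only where
#' no sponges of any kind were caught. Records with sponges present but no
#' identification of this taxon are excluded from both classes, because
#' surveys do not routinely identify sponges below phylum level and such
#' catches cannot be scored either way.
#'
#' @param records data.frame with columns \code{lon}, \code{lat},
#'   \code{taxon_ids} (semicolon-separated identified taxa, may be empty)
#'   and \code{total_sponge_present} (logical).
#' @param taxon taxon label to model.
#' @param knownTaxa vector of valid taxon labels (for error checking);
#'   default: all labels occurring in \code{records}.
#' @param subarea label stored on the resulting set.
#' @return an \code{\link{OccurrenceSet}}; excluded records are dropped.
#' @export
buildTaxonOccurrences <- function(records, taxon, knownTaxa = NULL,
                                  subarea = unique(records$subarea)) {
  ids <- strsplit(ifelse(is.na(records$taxon_ids), "", records$taxon_ids),
                  ";", fixed = TRUE)
  ids <- lapply(ids, trimws)
  if (is.null(knownTaxa)) knownTaxa <- unique(unlist(ids))
  if (!(taxon %in% knownTaxa)) stop("unknown taxon label: ", taxon)
  has <- vapply(ids, function(x) taxon %in% x, logical(1))
  lab <- rep(NA_character_, nrow(records))
  lab[has] <- "presence"
  lab[!has & !records$total_sponge_present] <- "absence"
  keep <- !is.na(lab)
  new("OccurrenceSet", response = taxon,
      subarea = paste(subarea, collapse = "+"),
      records = data.frame(
        lon = records$lon[keep], lat = records$lat[keep],
        label = factor(lab[keep], levels = c("absence", "presence"))))
}

#' Assign subarea labels to records by mask containment
#'
#' Labels each record with the first mask (in declared order) whose valid
#' cells contain its position; records on a shared boundary therefore go to
#' the first mask, with a warning when any record falls in more than one
#' mask. Records outside all masks receive the full-area tag only — they
#' remain usable for full-area models.
#'
#' @param records data.frame with \code{lon}, \code{lat}.
#' @param masks named list of 1/NA \code{Grid} masks (declared order is the
#'   tie-break order).
#' @param fullAreaTag label for records outside every mask.
#' @return \code{records} with a (re)written \code{subarea} column.
#' @export
assignSubarea <- function(records, masks, fullAreaTag = "full-area") {
  n <- nrow(records)
  hits <- matrix(FALSE, n, length(masks))
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    idx <- cellIndex(m, records$lon, records$lat)
    inside <- !is.na(idx[, 1L])
    v <- rep(NA_real_, n)
    v[inside] <- m@values[cbind(idx[inside, 1L], idx[inside, 2L])]
    hits[, k] <- !is.na(v)
  }
  nHit <- rowSums(hits)
  if (any(nHit > 1L))
    warning(sum(nHit > 1L),
            " record(s) fall in multiple masks; assigned to the first in ",
            "declared order")
  first <- apply(hits, 1L, function(h) which(h)[1L])
  lab <- ifelse(nHit == 0L, fullAreaTag, names(masks)[first])
  records$subarea <- lab
  records
}

#' Check an occurrence set is large enough to model
#'
#' @param occ an \code{\link{OccurrenceSet}}.
#' @param minPresences minimum presences required (default 15, the customary
#'   smallest class size for attempting species-level distribution models).
#' @param minAbsences minimum absences required.
#' @return TRUE invisibly, or an error describing the deficit.
#' @export
checkModelable <- function(occ, minPresences = 15, minAbsences = 15) {
  tab <- table(occurrenceRecords(occ)$label)
  if (tab[["presence"]] < minPresences)
    stop(sprintf("only %d presences (< %d) for response '%s'",
                 tab[["presence"]], minPresences, responseLabel(occ)))
  if (tab[["absence"]] < minAbsences)
    stop(sprintf("only %d absences (< %d) for response '%s'",
                 tab[["absence"]], minAbsences, responseLabel(occ)))
  invisible(TRUE)
}
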