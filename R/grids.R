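# Environmental-layer engineering: constructors, temporal statistics,
# bilinear resampling, slope from bathymetry, point extraction.

#' Create a Grid
#'
#' @param values numeric matrix; row 1 = northernmost row, NA = nodata.
#' @param origin lon/lat (degrees) of the center of the north-west cell.
#' @param cellSize cell size in decimal degrees.
#' @param name predictor label.
#' @param units free-text units.
#' @return a \code{\link{Grid}}.
#' @export
Grid <- function(values, origin, cellSize, name, units = "") {
  storage.mode(values) <- "double"
  new("Grid", values = values, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), name = name, units = units)
}

#' Create a GridStack from Grid objects
#'
#' @param ... \code{Grid} objects, or a single list of them.
#' @return a \code{\link{GridStack}} keyed by the grids' names.
#' @export
GridStack <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1L]]) && !is(gs[[1L]], "Grid"))
    gs <- gs[[1L]]
  names(gs) <- vapply(gs, gridName, character(1))
  new("GridStack", grids = gs)
}

#' Replace the value matrix of a Grid (geometry preserved)
#'
#' @param grid a \code{Grid}.
#' @param values replacement matrix of identical shape.
#' @param name,units optional new labels.
#' @return a \code{Grid}.
#' @export
withValues <- function(grid, values, name = gridName(grid),
                       units = gridUnits(grid)) {
  stopifnot(identical(dim(values), dim(grid@values)))
  Grid(values, grid@origin, grid@cellSize, name, units)
}

geometryOf <- function(x) {
  list(origin = gridOrigin(x), cellSize = cellSize(x), dim = gridDim(x))
}

sameGeometry <- function(a, b) {
  identical(gridOrigin(a), gridOrigin(b)) &&
    identical(cellSize(a), cellSize(b)) &&
    identical(gridDim(a), gridDim(b))
}

# lon/lat of cell centers
cellLons <- function(grid) grid@origin[1] + (seq_len(ncol(grid@values)) - 1L) * grid@cellSize
cellLats <- function(grid) grid@origin[2] - (seq_len(nrow(grid@values)) - 1L) * grid@cellSize

# nearest containing cell; returns matrix [row, col], NA outside extent
cellIndex <- function(grid, lon, lat) {
  cs <- grid@cellSize
  j <- round((lon - grid@origin[1]) / cs) + 1L
  i <- round((grid@origin[2] - lat) / cs) + 1L
  d <- dim(grid@values)
  bad <- i < 1L | i > d[1] | j < 1L | j > d[2]
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = i, col = j)
}

#' Per-cell temporal statistics over a sequence of co-registered layers
#'
#' Computes per-cell minimum, mean, maximum and/or range over a temporal
#' sequence of layers (e.g. ten annual chlorophyll composites, or 3-hourly
#' bottom-temperature fields). Nodata is propagated strictly: a cell missing
#' in any input layer is missing in every output, which avoids minima/maxima
#' biased by partial temporal coverage. Range is max minus min.
#'
#' @param layers list of co-registered \code{Grid} objects (the sequence).
#' @param metrics subset of c("min", "mean", "max", "range").
#' @param baseName stem for output layer names; outputs are named
#'   \code{<baseName>_<metric>}.
#' @param units units label carried to the outputs.
#' @return a \code{\link{GridStack}} with one layer per metric.
#' @export
temporalStatistics <- function(layers,
                               metrics = c("min", "mean", "max", "range"),
                               baseName = gridName(layers[[1L]]),
                               units = gridUnits(layers[[1L]])) {
  if (length(layers) == 0L) stop("temporalStatistics: empty layer list")
  metrics <- match.arg(metrics, several.ok = TRUE)
  ref <- layers[[1L]]
  for (g in layers)
    if (!sameGeometry(g, ref))
      stop(sprintf("temporalStatistics: layer '%s' geometry mismatch",
                   gridName(g)))
  arr <- vapply(layers, function(g) g@values, ref@values)
  dim(arr) <- c(dim(ref@values), length(layers))
  anyNA <- apply(is.na(arr), c(1, 2), any)
  mn <- apply(arr, c(1, 2), min)
  mx <- apply(arr, c(1, 2), max)
  stat <- list(min = mn, mean = apply(arr, c(1, 2), mean),
               max = mx, range = mx - mn)
  out <- lapply(metrics, function(m) {
    v <- stat[[m]]
    v[anyNA] <- NA_real_
    Grid(v, ref@origin, ref@cellSize, paste(baseName, m, sep = "_"), units)
  })
  GridStack(out)
}

#' Bilinearly resample a grid to a target geometry
#'
#' Interpolates a continuous field to the cell centers of a target geometry
#' using bilinear interpolation between the four surrounding source cell
#' centers. Nodata is propagated conservatively: if any source cell with
#' positive interpolation weight is nodata, the target cell is nodata.
#' Target cells outside the source cell-center hull are nodata.
#'
#' @param src a \code{Grid}.
#' @param target a \code{Grid}, \code{GridStack}, or a list with elements
#'   \code{origin}, \code{cellSize}, \code{dim} describing the target.
#' @return a \code{Grid} on the target geometry.
#' @export
resampleGrid <- function(src, target) {
  tg <- if (is(target, "Grid") || is(target, "GridStack")) geometryOf(target)
        else target
  nr <- tg$dim[1]; nc <- tg$dim[2]
  lons <- tg$origin[1] + (seq_len(nc) - 1L) * tg$cellSize
  lats <- tg$origin[2] - (seq_len(nr) - 1L) * tg$cellSize
  cs <- src@cellSize
  sv <- src@values
  sd <- dim(sv)
  # fractional source coordinates of each target center (0-based)
  tj <- (lons - src@origin[1]) / cs
  ti <- (src@origin[2] - lats) / cs
  eps <- 1e-9
  out <- matrix(NA_real_, nr, nc)
  insideJ <- tj >= -eps & tj <= (sd[2] - 1L) + eps
  insideI <- ti >= -eps & ti <= (sd[1] - 1L) + eps
  if (!any(insideI) || !any(insideJ))
    stop("resampleGrid: target does not overlap the source grid")
  for (i in which(insideI)) {
    yi <- min(max(ti[i], 0), sd[1] - 1L)
    i0 <- floor(yi); wi <- yi - i0
    if (wi < eps) { wi <- 0 } else if (wi > 1 - eps) { i0 <- i0 + 1; wi <- 0 }
    for (j in which(insideJ)) {
      xj <- min(max(tj[j], 0), sd[2] - 1L)
      j0 <- floor(xj); wj <- xj - j0
      if (wj < eps) { wj <- 0 } else if (wj > 1 - eps) { j0 <- j0 + 1; wj <- 0 }
      i1 <- i0 + 1L; j1 <- j0 + 1L  # 1-based corner
      v00 <- sv[i1, j1]
      acc <- (1 - wi) * (1 - wj) * v00
      if (wj > 0) acc <- acc + (1 - wi) * wj * sv[i1, j1 + 1L]
      if (wi > 0) acc <- acc + wi * (1 - wj) * sv[i1 + 1L, j1]
      if (wi > 0 && wj > 0) acc <- acc + wi * wj * sv[i1 + 1L, j1 + 1L]
      out[i, j] <- acc
    }
  }
  Grid(out, tg$origin, tg$cellSize, src@name, src@units)
}

#' Seafloor slope from a bathymetry grid
#'
#' Derives slope in degrees using Horn's 8-neighbor finite-difference
#' gradient. East-west cell widths are scaled by cos(latitude) of each row so
#' that gradients are taken in meters on the ground; depth must be in meters.
#' Border cells and cells with any missing neighbor are nodata. Adding a
#' constant to depth leaves the slope unchanged.
#'
#' @param depth a \code{Grid} of depth in meters (sign convention free).
#' @param metersPerDegree meters per degree of latitude (WGS84 mean).
#' @return a \code{Grid} named "slope", units degrees.
#' @export
slopeFromDepth <- function(depth, metersPerDegree = 111320) {
  z <- depth@values
  d <- dim(z)
  if (d[1] < 3L || d[2] < 3L) stop("slopeFromDepth: grid smaller than 3x3")
  lat <- cellLats(depth)
  dy <- depth@cellSize * metersPerDegree
  dx <- dy * cos(lat * pi / 180)   # per-row east-west width
  ri <- 2:(d[1] - 1L); cj <- 2:(d[2] - 1L)
  # 3x3 neighborhood shifts (interior)
  z1 <- z[ri - 1L, cj - 1L]; z2 <- z[ri - 1L, cj]; z3 <- z[ri - 1L, cj + 1L]
  z4 <- z[ri,      cj - 1L];                        z6 <- z[ri,      cj + 1L]
  z7 <- z[ri + 1L, cj - 1L]; z8 <- z[ri + 1L, cj]; z9 <- z[ri + 1L, cj + 1L]
  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dx[ri])
  gy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * dy)
  out <- matrix(NA_real_, d[1], d[2])
  out[ri, cj] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  Grid(out, depth@origin, depth@cellSize, "slope", "degrees")
}

#' Extract predictor values at point locations
#'
#' Looks up, for each point, the value of the cell containing it in every
#' layer of the stack (nearest-cell rule: trawls are treated as point
#' observations at their start position). Points outside the stack extent
#' are flagged rather than failing the call; rows with any nodata predictor
#' are flagged as incomplete and should be excluded from modeling.
#'
#' @param stack a \code{\link{GridStack}}.
#' @param points data.frame with columns \code{lon} and \code{lat}.
#' @return data.frame: one column per layer, plus logical \code{in_extent}
#'   and \code{complete} flags.
#' @export
extractAtPoints <- function(stack, points) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  ref <- stack@grids[[1L]]
  idx <- cellIndex(ref, points$lon, points$lat)
  n <- nrow(points)
  out <- data.frame(row.names = seq_len(n))
  flat <- ifelse(is.na(idx[, 1L]), NA_integer_,
                 idx[, 1L] + (idx[, 2L] - 1L) * nrow(ref@values))
  for (nm in names(stack@grids)) {
    v <- rep(NA_real_, n)
    ok <- !is.na(flat)
    v[ok] <- stack@grids[[nm]]@values[flat[ok]]
    out[[nm]] <- v
  }
  out$in_extent <- !is.na(flat)
  out$complete <- out$in_extent &
    !apply(is.na(as.matrix(out[names(stack@grids)])), 1L, any)
  out
}
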