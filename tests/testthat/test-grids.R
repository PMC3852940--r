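# Environmental-layer engineering: temporal statistics, resampling, slope,
# point extraction.

makeGrid <- function(v, name = "x", origin = c(0, 1), cs = 0.1)
  Grid(v, origin, cs, name)

test_that("temporal statistics reduce layer sequences cellwise", {
  g1 <- makeGrid(matrix(1, 4, 5))
  # degenerate single-layer sequence: min = mean = max = input, range = 0
  st1 <- temporalStatistics(list(g1))
  expect_equal(gridValues(st1[["x_min"]]), gridValues(g1))
  expect_equal(gridValues(st1[["x_mean"]]), gridValues(g1))
  expect_equal(gridValues(st1[["x_max"]]), gridValues(g1))
  expect_true(all(gridValues(st1[["x_range"]]) == 0))

  # forced arithmetic on a two-layer sequence with values 1 and 3
  st2 <- temporalStatistics(list(g1, makeGrid(matrix(3, 4, 5))))
  expect_true(all(gridValues(st2[["x_min"]]) == 1))
  expect_true(all(gridValues(st2[["x_max"]]) == 3))
  expect_true(all(gridValues(st2[["x_mean"]]) == 2))
  expect_true(all(gridValues(st2[["x_range"]]) == 2))
})

test_that("temporal statistics obey order-statistic inequalities on noise", {
  set.seed(7)
  layers <- lapply(1:12, function(i) makeGrid(matrix(runif(20 * 25), 20)))
  st <- temporalStatistics(layers)
  rng <- gridValues(st[["x_range"]])
  expect_true(all(rng >= 0 & rng <= 1))
  expect_true(all(rng >= gridValues(st[["x_max"]]) -
                    gridValues(st[["x_mean"]])))
  # range = max - min holds cellwise
  expect_equal(rng, gridValues(st[["x_max"]]) - gridValues(st[["x_min"]]))
})

test_that("temporal statistics propagate nodata strictly and check geometry", {
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  st <- temporalStatistics(list(makeGrid(v), makeGrid(matrix(2, 3, 3))))
  expect_true(all(is.na(gridValues(st[["x_min"]])[2, 2])))
  expect_false(anyNA(gridValues(st[["x_min"]])[-5]))
  expect_error(temporalStatistics(list()), "empty")
  expect_error(
    temporalStatistics(list(makeGrid(v), makeGrid(matrix(1, 4, 3)))),
    "geometry")
})

test_that("identity resampling returns the source values", {
  set.seed(1)
  g <- makeGrid(matrix(rnorm(30), 5, 6))
  out <- resampleGrid(g, g)
  expect_equal(gridValues(out), gridValues(g))
})

test_that("bilinear resampling is exact for constants and planes", {
  cons <- makeGrid(matrix(4.2, 6, 6), cs = 0.3)
  fine <- list(origin = c(0.05, 0.95), cellSize = 0.1, dim = c(12L, 12L))
  expect_true(all(abs(gridValues(resampleGrid(cons, fine)) - 4.2) < 1e-12,
                  na.rm = TRUE))

  ramp <- planarRampGrid(nr = 8, nc = 8, a = 2, bLon = 3, bLat = -1.5,
                         cs = 0.3, origin = c(0, 2))
  tgt <- list(origin = c(0.1, 1.9), cellSize = 0.1, dim = c(18L, 18L))
  out <- resampleGrid(ramp, tgt)
  lons <- tgt$origin[1] + (seq_len(18) - 1) * 0.1
  lats <- tgt$origin[2] - (seq_len(18) - 1) * 0.1
  expected <- outer(lats, lons, function(la, lo) 2 + 3 * lo - 1.5 * la)
  ok <- !is.na(gridValues(out))
  expect_true(any(ok))
  expect_lt(max(abs(gridValues(out) - expected)[ok]), 1e-9)
})

test_that("resampling propagates nodata conservatively and flags no overlap", {
  v <- matrix(1:16, 4, 4); v[2, 2] <- NA
  g <- makeGrid(v, cs = 0.2, origin = c(0, 1))
  fine <- list(origin = c(0.05, 0.97), cellSize = 0.07, dim = c(8L, 8L))
  out <- resampleGrid(g, fine)
  # any target cell drawing weight from the missing source cell is missing
  expect_gt(sum(is.na(gridValues(out))), 0)
  far <- list(origin = c(50, 60), cellSize = 0.1, dim = c(4L, 4L))
  expect_error(resampleGrid(g, far), "overlap")
})

test_that("slope is zero on flat seafloor and matches a ramp analytically", {
  flat <- makeGrid(matrix(500, 10, 10), origin = c(0, 0.5), cs = 0.01)
  s <- slopeFromDepth(flat)
  inner <- gridValues(s)[2:9, 2:9]
  expect_true(all(abs(inner) < 1e-12))

  # north-south ramp of 10 m per 1000 m horizontal -> atan(0.01) = 0.573 deg
  mpd <- 111320
  dy <- 0.01 * mpd
  nr <- 12; nc <- 12
  v <- matrix(rep(seq_len(nr) * dy * 0.01, nc), nr, nc)
  ramp <- makeGrid(v, origin = c(0, 0.5), cs = 0.01)
  s2 <- slopeFromDepth(ramp)
  expect_equal(gridValues(s2)[5, 5], atan(0.01) * 180 / pi,
               tolerance = 1e-6)
  # transposed ramp near the equator: same magnitude (isotropy)
  rampT <- makeGrid(t(v), origin = c(0, 0.002), cs = 0.01)
  s3 <- slopeFromDepth(rampT)
  expect_equal(gridValues(s3)[5, 5], atan(0.01) * 180 / pi,
               tolerance = 1e-3)
})

test_that("slope is invariant to a constant depth offset and needs 3x3", {
  set.seed(3)
  v <- matrix(500 + rnorm(100, sd = 40), 10, 10)
  g <- makeGrid(v, origin = c(-50, 60), cs = 0.01)
  g2 <- makeGrid(v + 1234, origin = c(-50, 60), cs = 0.01)
  expect_equal(gridValues(slopeFromDepth(g)), gridValues(slopeFromDepth(g2)))
  expect_error(slopeFromDepth(makeGrid(matrix(1, 2, 2))), "3x3")
})

test_that("point extraction uses the containing cell and flags bad rows", {
  v <- matrix(as.numeric(1:12), 3, 4)
  v[2, 3] <- NA
  g <- makeGrid(v, origin = c(0, 1), cs = 0.1, name = "a")
  st <- GridStack(g, makeGrid(v * 10, origin = c(0, 1), cs = 0.1,
                              name = "b"))
  pts <- data.frame(lon = c(0.1, 0.2, 9.0), lat = c(1.0, 0.9, 1.0))
  out <- extractAtPoints(st, pts)
  expect_equal(out$a[1], v[1, 2])           # exact cell center
  expect_true(is.na(out$a[2]) && !out$complete[2])  # nodata cell flagged
  expect_true(out$in_extent[1] && !out$in_extent[3])
  expect_false(out$complete[3])
})

test_that("extraction on a planar ramp is within one cell width of the plane", {
  g <- planarRampGrid(nr = 30, nc = 30, a = 1, bLon = 2, bLat = 3,
                      origin = c(10, 40), cs = 0.05)
  st <- GridStack(g)
  set.seed(9)
  n <- 1000
  pts <- data.frame(lon = runif(n, 10, 10 + 29 * 0.05),
                    lat = runif(n, 40 - 29 * 0.05, 40))
  out <- extractAtPoints(st, pts)
  truth <- 1 + 2 * pts$lon + 3 * pts$lat
  # nearest-cell lookup error is bounded by the plane's variation per cell
  bound <- (abs(2) + abs(3)) * 0.05
  expect_true(all(abs(out$ramp - truth) <= bound + 1e-12))
})

test_that("operation outputs share the declared geometry exactly", {
  g <- planarRampGrid(nr = 6, nc = 7)
  st <- temporalStatistics(list(g, g))
  expect_identical(gridOrigin(st), gridOrigin(g))
  expect_identical(cellSize(st), cellSize(g))
  s <- slopeFromDepth(g)
  expect_identical(gridOrigin(s), gridOrigin(g))
  expect_identical(gridDim(s), gridDim(g))
  r <- resampleGrid(g, g)
  expect_identical(gridOrigin(r), gridOrigin(g))
})
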