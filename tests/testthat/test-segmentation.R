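test_that("gradient cost puts per-column minima on the matching edge", {
  img <- matrix(0.1, 10, 6)
  img[5, ] <- 0.9                       # single bright row
  cdb <- gradientCost(img, "dark_to_bright")
  expect_equal(unname(apply(cdb, 2, which.min)), rep(4L, 6L))
  cbd <- gradientCost(img, "bright_to_dark")
  expect_equal(unname(apply(cbd, 2, which.min)), rep(6L, 6L))
  ## constant image: all costs equal
  cc <- gradientCost(matrix(0.5, 5, 5), "dark_to_bright")
  expect_equal(max(cc) - min(cc), 0)
  expect_true(all(cc > 0))
  expect_error(gradientCost(matrix(1, 1, 5)), "2 rows")
})

test_that("shortest path matches exhaustive enumeration on small grids", {
  set.seed(42)
  for (nr in 2:6) for (nc in 2:6) {
    cost <- matrix(runif(nr * nc, 0.1, 1), nr, nc)
    tr <- shortestPathBoundary(cost, maxStep = 1L, refine = FALSE)
    expect_equal(attr(tr@position, "totalCost"),
                 bruteForcePathCost(cost, 1L), tolerance = 1e-12)
  }
  ## larger step bound
  cost <- matrix(runif(36, 0.1, 1), 6, 6)
  tr <- shortestPathBoundary(cost, maxStep = 2L, refine = FALSE)
  expect_equal(attr(tr@position, "totalCost"), bruteForcePathCost(cost, 2L))
})

test_that("banded search returns the within-band optimum", {
  set.seed(7)
  cost <- matrix(runif(30, 0.1, 1), 6, 5)
  cost[1, ] <- 0.01                     # global optimum outside the band
  band <- rbind(rep(3, 5), rep(6, 5))
  tr <- shortestPathBoundary(cost, band, maxStep = 1L, refine = FALSE)
  expect_equal(attr(tr@position, "totalCost"),
               bruteForcePathCost(cost, 1L, band))
  expect_true(all(attr(tr@position, "pathRow") >= 3))
  expect_error(shortestPathBoundary(cost, rbind(rep(6, 5), rep(3, 5))),
               "empty")
  ## infeasible band jump under the step bound
  band2 <- rbind(c(1, 6, 1, 1, 1), c(2, 6, 2, 2, 2))
  expect_error(shortestPathBoundary(cost, band2, maxStep = 1L), "infeasible")
})

test_that("a zero-cost row is the unique optimum and ties are deterministic", {
  cost <- matrix(1, 8, 8)
  cost[4, ] <- 1e-6
  tr <- shortestPathBoundary(cost, maxStep = 1L, refine = FALSE)
  expect_equal(unname(attr(tr@position, "pathRow")), rep(4L, 8L))
  ## all-equal costs: tie-break keeps the flat upper-row path
  flat <- shortestPathBoundary(matrix(1, 6, 6), maxStep = 2L, refine = FALSE)
  expect_equal(unname(attr(flat@position, "pathRow")), rep(1L, 6L))
})

test_that("sub-pixel refinement recovers partial-volume edge positions", {
  ## boundary at row 6.3: pixel 6 blends the two tissues
  b <- 6.3
  col <- 0.1 + 0.7 * pmin(pmax(seq_len(12) + 0.5 - b, 0), 1)
  img <- matrix(rep(col, 5), 12, 5)
  tr <- shortestPathBoundary(gradientCost(img, "dark_to_bright"), maxStep = 1L)
  expect_equal(tr@position, rep(b, 5), tolerance = 0.02, ignore_attr = TRUE)
})

test_that("spline initialization interpolates, extrapolates and validates", {
  ## collinear seeds reproduce the line everywhere
  seeds <- cbind(c(10, 40, 80, 120), 5 + 0.1 * c(10, 40, 80, 120))
  tr <- splineInitBoundary(seeds, 150L)
  expect_equal(unname(tr@position), 5 + 0.1 * (1:150), tolerance = 1e-8)
  ## five points on a parabola stay close at midpoints
  xs <- c(10, 30, 50, 70, 90)
  tr2 <- splineInitBoundary(cbind(xs, 0.01 * xs^2), 100L)
  mid <- c(20, 40, 60, 80)
  expect_lt(max(abs(tr2@position[mid] - 0.01 * mid^2)), 0.5)
  expect_error(splineInitBoundary(cbind(10, 5), 100L), "2 seed points")
  expect_error(splineInitBoundary(cbind(c(10, 10), c(5, 6)), 100L),
               "distinct")
})

test_that("noiseless synthetic scans segment to within 1 px RMS", {
  fx <- renderedEye("normal")
  win <- windowColumns(fx$geom)
  for (reg in c("central", "inferior", "superior")) {
    bs <- segmentCornea(fx$scans[[reg]])
    truth <- groundTruthBoundaryRows(fx$gt, reg, fx$geom)$rows
    for (i in seq_along(bs@traces)) {
      tr <- bs@traces[[i]]
      use <- tr@valid & win
      expect_gt(sum(use), 100)
      err <- tr@position[use] - truth[i, use]
      expect_lt(sqrt(mean(err^2)), 1)
    }
  }
})

test_that("seed-point initialization confines the Bowman-stroma search", {
  fx <- renderedEye("normal")
  truth <- groundTruthBoundaryRows(fx$gt, "central", fx$geom)$rows
  cols <- round(seq(60, 450, length.out = 6))
  set.seed(1)
  seeds <- cbind(cols, truth["bowman_stroma", cols] + rnorm(6, sd = 0.5))
  bs <- segmentCornea(fx$scans$central, seeds = seeds)
  tr <- bs@traces$bowman_stroma
  use <- tr@valid & windowColumns(fx$geom)
  err <- tr@position[use] - truth["bowman_stroma", use]
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("manual corrections change exactly the stated columns", {
  fx <- renderedEye("normal")
  plain <- segmentCornea(fx$scans$central)
  corr <- segmentCornea(fx$scans$central,
                        corrections = list(list(interface = "bowman_stroma",
                                                columns = 100:200,
                                                offset = 2)))
  a <- plain@traces$bowman_stroma@position
  b <- corr@traces$bowman_stroma@position
  expect_equal(b[100:200], a[100:200] + 2)
  expect_equal(b[-(100:200)], a[-(100:200)])
  for (i in c("air_epithelium", "epithelium_bowman", "stroma_posterior"))
    expect_equal(corr@traces[[i]]@position, plain@traces[[i]]@position)
})

test_that("forced trace crossings are clipped, flagged and stay ordered", {
  fx <- renderedEye("normal")
  bs <- segmentCornea(fx$scans$central,
                      corrections = list(list(interface = "bowman_stroma",
                                              columns = 150:160,
                                              offset = -60)))
  expect_true(all(150:160 %in% bs@clipped))
  expect_true(validObject(bs))
  p2 <- bs@traces$epithelium_bowman@position
  p3 <- bs@traces$bowman_stroma@position
  both <- bs@traces$epithelium_bowman@valid & bs@traces$bowman_stroma@valid
  expect_true(all(p3[both] >= p2[both] - 1e-9))
})

test_that("segmentation refuses a featureless image", {
  g <- scanGeometry(64L, 32L)
  flat <- new("BScan", intensity = matrix(0.5, 64, 32),
              region = "central", geometry = g)
  expect_error(segmentCornea(flat), "surface")
})

test_that("segmentation error grows monotonically with rendering noise", {
  fx <- renderedEye("normal")
  rms <- vapply(c(0, 0.03, 0.1), function(ns) {
    b <- renderBScan(fx$gt, "central", fx$geom, seed = 5, noiseSD = ns)
    bs <- segmentCornea(b)
    truth <- groundTruthBoundaryRows(fx$gt, "central", fx$geom)$rows
    tr <- bs@traces$air_epithelium
    use <- tr@valid & windowColumns(fx$geom)
    sqrt(mean((tr@position[use] - truth[1, use])^2))
  }, 0)
  expect_true(all(diff(rms) >= -0.02))
})
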