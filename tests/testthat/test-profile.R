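## boundary set with a prescribed Bowman-stroma validity mask
maskedBoundarySet <- function(valid, region = "inferior",
                              geometry = scanGeometry(64L, length(valid))) {
  nc <- length(valid)
  mk <- function(iface, rows, v = rep(TRUE, nc)) {
    pos <- rows; pos[!v] <- NA_real_
    new("BoundaryTrace", interface = iface, position = pos, valid = v)
  }
  traces <- list(
    air_epithelium = mk("air_epithelium", rep(10, nc)),
    epithelium_bowman = mk("epithelium_bowman", rep(20, nc)),
    bowman_stroma = mk("bowman_stroma", rep(25, nc), valid),
    stroma_posterior = mk("stroma_posterior", rep(50, nc)))
  new("BoundarySet", traces = traces, region = region, geometry = geometry,
      clipped = integer(0))
}

test_that("edges are the termini of the valid run", {
  v <- rep(FALSE, 2048); v[100:1900] <- TRUE
  e <- detectBowmanEdges(maskedBoundarySet(v))
  expect_equal(e[["inferior"]], 100L)
  expect_equal(e[["superior"]], 1900L)
})

test_that("a central scan with no termination returns an empty edge set", {
  v <- rep(TRUE, 512)
  e <- detectBowmanEdges(maskedBoundarySet(v, region = "central"))
  expect_length(e, 0L)
})

test_that("small validity gaps are closed when locating the terminus", {
  v <- rep(FALSE, 1000); v[200:800] <- TRUE
  v[400:402] <- FALSE                     # 3-column dropout
  e <- detectBowmanEdges(maskedBoundarySet(v))
  expect_equal(unname(e), c(200L, 800L))
  ## a gap beyond tolerance splits the run
  v2 <- rep(FALSE, 1000); v2[200:800] <- TRUE; v2[300:320] <- FALSE
  e2 <- detectBowmanEdges(maskedBoundarySet(v2))
  expect_equal(e2[["inferior"]], 321L)
})

test_that("peripheral scan without an in-view edge errors", {
  v <- rep(TRUE, 512)
  expect_error(detectBowmanEdges(maskedBoundarySet(v, region = "inferior")),
               "edge not in view")
})

## thickness profile with prescribed values over the full width
makeThickness <- function(values, region, geometry, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  new("AScanThicknessProfile", layer = "epithelium",
      thickness = values, lateral = seq_along(values) * lateralPitch(geometry),
      valid = valid, region = region, geometry = geometry)
}

test_that("zonal averaging reproduces block means in order", {
  g <- scanGeometry(64L, 1200L)           # window of 240 A-scans
  W <- windowAScans(g)
  th <- makeThickness(rep(50, 1200), "central", g)
  zp <- zonalAverage(th, apexCol = 600L)
  expect_equal(zp@zoneMeans, rep(50, 10))
  ## linear ramp 40 -> 60 over the window gives means 41, 43, ..., 59
  vals <- rep(NA_real_, 1200)
  start <- 600L - W %/% 2 + 1L
  vals[start:(start + W - 1L)] <- seq(40, 60, length.out = W + 1)[1:W]
  vals[is.na(vals)] <- 1
  zp2 <- zonalAverage(makeThickness(vals, "central", g), apexCol = 600L)
  expect_equal(zp2@zoneMeans, seq(41, 59, by = 2), tolerance = 0.06)
})

test_that("invalid A-scans are excluded and partial zones flagged", {
  g <- scanGeometry(64L, 1200L)
  W <- windowAScans(g)
  vals <- rep(50, 1200)
  valid <- rep(TRUE, 1200)
  start <- 600L - W %/% 2 + 1L
  ## poison most of zone 2 with an invalid excursion
  z2 <- start + (W %/% 10):(2 * W %/% 10 - 1)
  vals[z2] <- 500
  valid[z2[-1]] <- FALSE
  zp <- zonalAverage(makeThickness(vals, "central", g, valid), apexCol = 600L)
  expect_true(zp@partial[2])
  expect_false(any(zp@partial[-2]))
  expect_equal(zp@zoneMeans[1], 50)
  expect_equal(zp@zoneN[2], 1L)
})

test_that("windows anchored at edges and truncation is detected", {
  g <- scanGeometry(64L, 1200L)
  th <- makeThickness(seq_len(1200), "inferior", g)
  per <- windowAScans(g) %/% 10L
  zp <- zonalAverage(th, edges = c(inferior = 101L))
  expect_equal(zp@zoneMeans[1], mean(101:(100L + per)))  # first block mean
  expect_error(zonalAverage(th, edges = c(inferior = 1100L)), "truncated")
  expect_error(zonalAverage(th), "edge")
  thc <- makeThickness(seq_len(1200), "central", g)
  expect_error(zonalAverage(thc), "apex")
})

test_that("registration of exactly overlapping regions is lossless", {
  ## continuous ground-truth profile sampled per region at exact anchors
  w <- 0.423; S <- 13L
  f <- function(s) 55 - 0.3 * s - 0.15 * s^2
  binMean <- function(j) mean(f(seq(j * w, (j + 1) * w, length.out = 9)))
  zones <- function(start) vapply(0:9, function(k) binMean(start + k), 0)
  vp <- registerVerticalProfile(
    makeZonal("inferior", zones(-S), zoneChord = w),
    makeZonal("central", zones(-5), zoneChord = w),
    makeZonal("superior", zones(S - 10), zoneChord = w),
    semiSpanBins = S)
  expect_length(vp@values, 26L)
  expect_equal(vp@binIndex, seq(-13L, 12L))
  want <- vapply(vp@binIndex, binMean, 0)
  expect_lt(max(abs(vp@values - want)), 0.5)
  expect_equal(max(abs(vp@values - want)), 0, tolerance = 1e-9)
  ## overlapping bins carry two regions
  expect_equal(vp@nRegions[vp@binIndex %in% c(-5L, -4L, 3L, 4L)], rep(2L, 4))
})

test_that("missing regions and wide gaps are rejected", {
  z <- makeZonal("central", rep(50, 10))
  expect_error(registerVerticalProfile(NULL, z,
                                       makeZonal("superior", rep(50, 10))),
               "missing inferior")
  expect_error(registerVerticalProfile(makeZonal("inferior", rep(50, 10)),
                                       z, makeZonal("superior", rep(50, 10)),
                                       semiSpanBins = 17L),
               "gap")
})

test_that("partial zones are excluded and bridged bins flagged", {
  w <- 0.423
  zi <- makeZonal("inferior", rep(50, 10), partial = c(rep(FALSE, 9), TRUE))
  zc <- makeZonal("central", rep(60, 10))
  zs <- makeZonal("superior", rep(50, 10))
  vp <- registerVerticalProfile(zi, zc, zs)
  ## bin -4 overlaps: partial inferior zone drops out, central remains
  expect_equal(vp@values[vp@binIndex == -4L], 60)
  expect_true(all(vp@valid))
})

test_that("profile orientation matches the generator sign convention", {
  gt <- sampleCorneaGeometry(corneaParams("kc", coneCenter = -1.8), seed = 4)
  pr <- sampleEyeProfiles(gt, corneaParams("kc", coneCenter = -1.8), seed = 4)
  vp <- pr$epithelium
  ## the cone sits inferiorly: the thinnest bin must lie at negative chord
  expect_lt(binChord(vp)[which.min(vp@values)], 0)
})
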