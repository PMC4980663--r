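## build a BoundarySet from analytic traces (row positions per column)
makeBoundarySet <- function(rows, geometry, region = "central") {
  traces <- lapply(seq_len(4L), function(i)
    new("BoundaryTrace",
        interface = c("air_epithelium", "epithelium_bowman",
                      "bowman_stroma", "stroma_posterior")[i],
        position = rows[i, ], valid = rep(TRUE, ncol(rows))))
  names(traces) <- c("air_epithelium", "epithelium_bowman",
                     "bowman_stroma", "stroma_posterior")
  new("BoundarySet", traces = traces, geometry = geometry,
      region = region, clipped = integer(0))
}

flatRows <- function(geometry, depths_mm) {
  p <- geometry@axialExtentAir / geometry@axialPixels
  nc <- geometry@lateralPixels
  do.call(rbind, lapply(depths_mm, function(d) rep(d / p + 0.5, nc)))
}

test_that("normal incidence on a flat surface compresses depth by 1/n", {
  g <- scanGeometry(400L, 64L, refractiveIndex = 1.389)
  rows <- flatRows(g, c(0.2, 0.3, 0.35, 0.8))     # optical depths
  cb <- refractionCorrect(makeBoundarySet(rows, g))
  expect_equal(cb@lateral[2, ], cb@lateral[1, ], tolerance = 1e-9)
  expect_equal(cb@axial[2, ] - cb@axial[1, ], rep(0.1 / 1.389, 64),
               tolerance = 1e-9)
  expect_equal(cb@axial[4, ] - cb@axial[1, ], rep(0.6 / 1.389, 64),
               tolerance = 1e-9)
})

test_that("refractive index 1 makes the correction the identity", {
  g <- scanGeometry(400L, 64L, refractiveIndex = 1)
  p <- axialPitchAir(g)
  rows <- flatRows(g, c(0.2, 0.3, 0.35, 0.8)) + rep(seq(0, 0.3, length.out = 64),
                                                    each = 1)[col(matrix(0, 4, 64))]
  bs <- makeBoundarySet(rows, g)
  cb <- refractionCorrect(bs)
  for (i in 1:4) {
    expect_equal(cb@axial[i, ], (rows[i, ] - 0.5) * p, tolerance = 1e-9)
    expect_equal(cb@lateral[i, ], cb@lateral[1, ], tolerance = 1e-9)
  }
})

test_that("45-degree incidence refracts to asin(sin 45 / 1.389)", {
  ## plane surface tilted at 45 degrees: slope 1 in physical units
  g <- scanGeometry(3000L, 200L, axialExtentAir = 3, lateralExtent = 3,
                    refractiveIndex = 1.389)
  p <- axialPitchAir(g)
  u <- (seq_len(200) - 100.5) * lateralPitch(g)
  zsurf <- 1.5 + u                         # 45-degree plane
  delta <- 0.3                             # optical path below the surface
  rows <- rbind(zsurf / p + 0.5, (zsurf + delta) / p + 0.5,
                (zsurf + delta + 0.01) / p + 0.5,
                (zsurf + delta + 0.02) / p + 0.5)
  cb <- refractionCorrect(makeBoundarySet(rows, g))
  mid <- 100
  d <- c(cb@lateral[2, mid] - cb@lateral[1, mid],
         cb@axial[2, mid] - cb@axial[1, mid])
  ## angle between the refracted ray and the surface normal
  nrm <- c(1, -1) / sqrt(2)                # outward normal of z = x surface
  cosang <- sum(-d / sqrt(sum(d^2)) * nrm)
  thetaT <- acos(abs(cosang))
  expect_equal(thetaT, asin(sin(pi / 4) / 1.389), tolerance = 1e-3)
  ## and the geometric path equals optical path / n
  expect_equal(sqrt(sum(d^2)), delta / 1.389, tolerance = 1e-6)
})

test_that("a medium rarer than air triggers the TIR guard", {
  g <- scanGeometry(3000L, 200L, axialExtentAir = 3, lateralExtent = 3,
                    refractiveIndex = 0.5)
  p <- axialPitchAir(g)
  u <- (seq_len(200) - 100.5) * lateralPitch(g)
  zsurf <- 1.5 + u
  rows <- rbind(zsurf / p + 0.5, zsurf / p + 10, zsurf / p + 11, zsurf / p + 12)
  expect_error(refractionCorrect(makeBoundarySet(rows, g)),
               "total internal reflection")
})

test_that("parallel flat boundaries give constant perpendicular thickness", {
  g <- scanGeometry(400L, 64L, refractiveIndex = 1)
  rows <- flatRows(g, c(0.2, 0.25, 0.27, 0.8))
  cb <- refractionCorrect(makeBoundarySet(rows, g))
  th <- perpendicularThickness(cb, "epithelium")
  expect_equal(th@thickness[th@valid], rep(50, sum(th@valid)),
               tolerance = 1e-6)
})

test_that("tilted parallel plates measure s * cos(alpha)", {
  g <- scanGeometry(3000L, 200L, axialExtentAir = 3, lateralExtent = 3,
                    refractiveIndex = 1)
  p <- axialPitchAir(g)
  u <- (seq_len(200) - 100.5) * lateralPitch(g)
  alpha <- atan(0.5)                       # plate tilt
  s <- 0.2                                 # axial separation
  zsurf <- 1.2 + 0.5 * u
  rows <- rbind(zsurf / p + 0.5, (zsurf + s) / p + 0.5,
                (zsurf + s + 0.01) / p + 0.5, (zsurf + s + 0.02) / p + 0.5)
  cb <- refractionCorrect(makeBoundarySet(rows, g))
  th <- perpendicularThickness(cb, "epithelium")
  mid <- th@valid & abs(th@lateral) < 1
  expect_equal(mean(th@thickness[mid]) / 1000, s * cos(alpha),
               tolerance = 1e-4)
})

test_that("concentric arcs measure the radial gap everywhere", {
  R <- 7.8; t <- 0.05
  nc <- 256L
  u <- seq(-2.5, 2.5, length.out = nc)
  zu <- 0.2 + R - sqrt(R^2 - u^2)
  zl <- 0.2 + R - sqrt((R - t)^2 - u^2)
  lat <- rbind(u, u, u, u)
  ax <- rbind(zu, zl, zl + 0.01, zl + 0.02)
  rownames(lat) <- rownames(ax) <- c("air_epithelium", "epithelium_bowman",
                                     "bowman_stroma", "stroma_posterior")
  ok <- matrix(TRUE, 4, nc, dimnames = dimnames(lat))
  cb <- new("CorrectedBoundarySet", lateral = lat, axial = ax, valid = ok,
            region = "central", geometry = scanGeometry(lateralPixels = nc,
                                                        lateralExtent = 5))
  th <- perpendicularThickness(cb, "epithelium")
  mid <- th@valid & abs(th@lateral) < 2
  expect_equal(th@thickness[mid], rep(50, sum(mid)), tolerance = 0.25)
})

test_that("perpendicular thickness is invariant under rigid rotation", {
  R <- 7.8; t <- 0.06
  nc <- 256L
  u <- seq(-2.2, 2.2, length.out = nc)
  zu <- R - sqrt(R^2 - u^2)
  zl <- R - sqrt((R - t)^2 - u^2)
  mk <- function(phi) {
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    up <- rot %*% rbind(u, zu); lo <- rot %*% rbind(u, zl)
    lat <- rbind(up[1, ], lo[1, ], lo[1, ], lo[1, ])
    ax <- rbind(up[2, ], lo[2, ], lo[2, ] + 0.01, lo[2, ] + 0.02)
    rownames(lat) <- rownames(ax) <- c("air_epithelium", "epithelium_bowman",
                                       "bowman_stroma", "stroma_posterior")
    new("CorrectedBoundarySet", lateral = lat, axial = ax,
        valid = matrix(TRUE, 4, nc, dimnames = dimnames(lat)),
        region = "central",
        geometry = scanGeometry(lateralPixels = nc, lateralExtent = 5))
  }
  t0 <- perpendicularThickness(mk(0), "epithelium")
  t1 <- perpendicularThickness(mk(0.09), "epithelium")
  m0 <- t0@valid & abs(t0@lateral) < 1.5
  m1 <- t1@valid
  expect_equal(mean(t0@thickness[m0]), 60, tolerance = 0.3)
  expect_equal(mean(t1@thickness[m1 & abs(t1@lateral) < 1.5], na.rm = TRUE),
               mean(t0@thickness[m0]), tolerance = 0.3)
})
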