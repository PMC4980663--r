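## Smoothed finite-difference slope dz/dx on a regular lateral grid.
## Half-width shrinks near the ends so every column gets an estimate.
.smoothedSlope <- function(x, z, halfWidth) {
  n <- length(z)
  k <- pmin(pmin(halfWidth, seq_len(n) - 1L), n - seq_len(n))
  k <- pmax(k, 1L)
  i <- seq_len(n)
  (z[pmin(i + k, n)] - z[pmax(i - k, 1L)]) /
    (x[pmin(i + k, n)] - x[pmax(i - k, 1L)])
}

#' Refraction-correct a boundary set by Snell ray tracing
#'
#' Converts pixel-space interface traces to geometric physical
#' coordinates.  For each A-scan the incidence angle is taken from the
#' local tangent of the anterior surface (smoothed finite difference over
#' +/- `smoothHalfWidth` A-scans), the transmitted ray direction follows
#' Snell's law (n1 = 1 in air, n2 the geometry's refractive index), and
#' the optical path below the surface is divided by n2 and laid along the
#' refracted ray.  Above the surface air is undeviated, so the anterior
#' trace maps directly to physical coordinates.  With a refractive index
#' of 1 the correction is the identity.
#'
#' @param boundaries a [BoundarySet-class].
#' @param geometry the scan geometry; defaults to the boundary set's own.
#' @param smoothHalfWidth half-width (A-scans, at the reference 2048-px
#'   sampling) of the tangent estimator; scaled with the actual sampling.
#' @return a [CorrectedBoundarySet-class] with positions in mm.
#' @export
refractionCorrect <- function(boundaries, geometry = boundaries@geometry,
                              smoothHalfWidth = 25L) {
  stopifnot(is(boundaries, "BoundarySet"))
  n2 <- geometry@refractiveIndex
  p <- axialPitchAir(geometry)
  u <- .columnLateral(geometry)
  nc <- length(u)
  surf <- boundaries@traces[["air_epithelium"]]
  if (!any(surf@valid))
    stop("anterior surface trace has no valid columns")
  zs <- (surf@position - 0.5) * p
  ## fill invalid surface columns by interpolation so the smoothed slope
  ## stays defined next to them (those columns stay flagged invalid)
  if (any(!surf@valid))
    zs[!surf@valid] <- stats::approx(u[surf@valid], zs[surf@valid],
                                     xout = u[!surf@valid], rule = 2)$y
  k <- max(3L, round(smoothHalfWidth * nc / 2048))
  slope <- .smoothedSlope(u, zs, k)
  norm <- sqrt(1 + slope^2)
  cosI <- 1 / norm
  sinI <- slope / norm            # signed; sign carries through the normal
  eta <- 1 / n2
  sinT2 <- (eta * sinI)^2
  if (any(sinT2 > 1, na.rm = TRUE))
    stop("total internal reflection: malformed anterior surface normals")
  cosT <- sqrt(1 - sinT2)
  ## n_out = (slope, -1)/norm; t = eta*d + (eta*cosI - cosT)*n_out
  a <- eta * cosI - cosT
  tx <- a * slope / norm
  tz <- eta - a * cosI

  lat <- ax <- matrix(NA_real_, 4L, nc, dimnames = list(.INTERFACES, NULL))
  ok <- matrix(FALSE, 4L, nc, dimnames = list(.INTERFACES, NULL))
  lat[1L, ] <- u; ax[1L, ] <- zs; ok[1L, ] <- surf@valid
  for (l in 2:4) {
    tr <- boundaries@traces[[l]]
    dist <- (tr@position - surf@position) * p / n2
    lat[l, ] <- u + dist * tx
    ax[l, ] <- zs + dist * tz
    ok[l, ] <- tr@valid & surf@valid & is.finite(dist)
  }
  new("CorrectedBoundarySet", lateral = lat, axial = ax, valid = ok,
      region = boundaries@region, geometry = geometry)
}

#' Apex A-scan of a corrected central image
#'
#' The A-scan of maximal anterior-surface elevation (minimal corrected
#' axial position), after light smoothing to suppress pixel noise.
#'
#' @param corrected a [CorrectedBoundarySet-class].
#' @return integer column index.
#' @export
apexColumn <- function(corrected) {
  z <- corrected@axial[1L, ]
  ok <- corrected@valid[1L, ]
  n <- length(z)
  if (any(!ok))
    z[!ok] <- stats::approx(which(ok), z[ok], xout = which(!ok), rule = 2)$y
  k <- max(5L, round(n / 80))
  sm <- as.numeric(stats::filter(z, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2))
  sm[is.na(sm) | !ok] <- Inf
  which.min(sm)
}

#' Layer thickness perpendicular to the anterior surface
#'
#' At each A-scan the distance from the layer's upper interface point to
#' its lower interface, measured along the local inward normal of the
#' anterior surface (the lower intersection found by interpolating the
#' lower trace), in micrometres.  Columns whose normal does not meet the
#' lower trace inside the scan are marked invalid.
#'
#' @param corrected a [CorrectedBoundarySet-class].
#' @param layer `"epithelium"` (air-epithelium to epithelium-Bowman),
#'   `"bowman"` or `"stroma"`.
#' @return an [AScanThicknessProfile-class].
#' @export
perpendicularThickness <- function(corrected, layer = .LAYERS) {
  layer <- match.arg(layer)
  l <- match(layer, .LAYERS)
  upper <- l; lower <- l + 1L
  lat <- corrected@lateral; ax <- corrected@axial; ok <- corrected@valid

  su <- ok[1L, ]
  if (sum(su) < 5L) stop("anterior surface required for the normal direction")
  k <- max(3L, round(25 * ncol(lat) / 2048))
  slope <- .smoothedSlope(lat[1L, ], ax[1L, ], k)
  slopeAt <- stats::approxfun(lat[1L, su], slope[su], rule = 2)

  lv <- ok[lower, ] & is.finite(lat[lower, ])
  if (sum(lv) < 2L) stop("lower interface of layer '", layer, "' has no valid columns")
  fLow <- stats::approxfun(lat[lower, lv], ax[lower, lv])
  xr <- range(lat[lower, lv])

  xu <- lat[upper, ]; zu <- ax[upper, ]
  m <- slopeAt(xu)
  nrm <- sqrt(1 + m^2)
  nx <- -m / nrm; nz <- 1 / nrm   # inward normal of the anterior surface
  t <- (fLow(pmin(pmax(xu, xr[1L]), xr[2L])) - zu) / nz
  for (it in 1:12) {
    xq <- xu + t * nx
    inside <- is.finite(xq) & xq >= xr[1L] & xq <= xr[2L]
    zq <- fLow(pmin(pmax(xq, xr[1L]), xr[2L]))
    tNew <- (zq - zu) / nz
    conv <- is.finite(t) & is.finite(tNew) & abs(tNew - t) < 1e-9
    t <- tNew
    if (all(conv | !inside, na.rm = TRUE)) break
  }
  xq <- xu + t * nx
  good <- ok[upper, ] & is.finite(t) & t > 0 &
    is.finite(xq) & xq >= xr[1L] & xq <= xr[2L]
  th <- t * 1000
  th[!good] <- NA_real_
  new("AScanThicknessProfile", layer = layer, thickness = th,
      lateral = xu, valid = good & !is.na(th),
      region = corrected@region, geometry = corrected@geometry)
}
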