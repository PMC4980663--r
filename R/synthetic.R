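## Regional window mean thicknesses (um) of the three diagnostic groups,
## layers x regions (inferior, central, superior), and their between-eye
## SDs.  These encode the group-wise zonal thickness structure the
## generator emulates: sub-clinical keratoconus shows mild central
## epithelial and inferior Bowman's-layer thinning, manifest keratoconus
## marked central thinning of all layers.
.REGIONAL_MEANS <- list(
  normal = matrix(c(54.94, 53.48, 50.91,
                    17.08, 17.07, 17.18,
                    533.30, 460.32, 525.27),
                  3L, 3L, byrow = TRUE,
                  dimnames = list(.LAYERS, .REGIONS)),
  subclinical_kc = matrix(c(54.85, 51.92, 50.27,
                            15.70, 16.02, 16.58,
                            509.67, 454.16, 512.04),
                          3L, 3L, byrow = TRUE,
                          dimnames = list(.LAYERS, .REGIONS)),
  kc = matrix(c(54.45, 46.10, 51.09,
                15.23, 12.06, 16.23,
                482.35, 412.49, 493.15),
              3L, 3L, byrow = TRUE,
              dimnames = list(.LAYERS, .REGIONS)))

.REGIONAL_SDS <- list(
  normal = matrix(c(2.80, 2.83, 3.09,
                    1.35, 1.51, 1.96,
                    29.03, 29.65, 32.64),
                  3L, 3L, byrow = TRUE,
                  dimnames = list(.LAYERS, .REGIONS)),
  subclinical_kc = matrix(c(3.36, 2.57, 3.02,
                            1.62, 2.10, 1.75,
                            38.32, 36.25, 40.82),
                          3L, 3L, byrow = TRUE,
                          dimnames = list(.LAYERS, .REGIONS)),
  kc = matrix(c(5.03, 5.31, 4.29,
                2.12, 2.50, 2.80,
                38.54, 39.19, 32.85),
              3L, 3L, byrow = TRUE,
              dimnames = list(.LAYERS, .REGIONS)))

## Localized (cone) thinning depth per layer (um).  Group-mean zonal
## tables understate per-subject localized dips (cone positions vary
## between eyes), so depths are set first-order from the published
## ectasia-index group means: the drop of EI below the normal value
## times the superior-half mean thickness gives the per-subject depth of
## the inferior minimum (sub-clinical: EEI 92.06 vs 100.36 on ~52 um ->
## ~5 um; BEI 77.10 vs 89.18 on ~16.5 um -> ~3.5 um; keratoconus:
## EEI 76.11 -> ~13 um, BEI 59.50 -> ~5 um, SEI 80.33 on ~500 um ->
## ~65 um after window-mean compensation).  Sub-clinical stromal indices
## show no separation, so the sub-clinical stromal cone is small.
.CONE_DEPTHS <- list(normal = c(0, 0, 0),
                     subclinical_kc = c(5, 3.5, 8),
                     kc = c(13, 5, 65))

## Anterior curvature radius (mm) per group, from average keratometry
## (337.5/K): 43.6 D normal, 43.5 D sub-clinical, 51.3 D keratoconus.
.ANTERIOR_RADIUS <- c(normal = 7.74, subclinical_kc = 7.76, kc = 6.58)

## Per-zone measurement noise SD (um) per layer, calibrated to the
## inter-grader repeatability of zonal thickness (about 1.2-1.7 um for
## epithelium and Bowman's layer; stroma assumed a few um).
.ZONE_NOISE_SD <- c(epithelium = 1.4, bowman = 1.25, stroma = 4)

#' Synthetic cohort parameters for a diagnostic group
#'
#' Builds the [SyntheticCorneaParams-class] of one group.  Defaults give
#' each group its published regional thickness structure: regional window
#' means and SDs per layer, a Gaussian cone of localized thinning whose
#' centre is drawn uniformly from the central-to-inferior meridian
#' (`coneCenterRange`), group-typical anterior curvature, and measurement
#' noise calibrated to inter-grader repeatability.
#'
#' @param group `"normal"`, `"subclinical_kc"` or `"kc"`.
#' @param anchorMeans,anchorSDs optional 3x3 overrides (layers x regions,
#'   regions ordered inferior/central/superior), um.
#' @param betweenEyeSD per-layer subject offset SD (um); default the mean
#'   regional SD of the group.
#' @param zoneNoiseSD per-layer per-zone noise SD (um).
#' @param coneCenter fixed cone centre (mm, negative = inferior), or NA
#'   to draw per eye from `coneCenterRange`.
#' @param coneCenterRange numeric(2), mm.
#' @param coneWidth Gaussian sigma (mm).
#' @param coneDepth per-layer maximal thinning (um).
#' @param anteriorRadius anterior curvature radius (mm).
#' @param bowmanEdgeArc arc distance apex to Bowman's layer edge (mm);
#'   the default (13 zone chords, about 5.50 mm) gives the canonical
#'   11-mm edge-to-edge profile.
#' @param noiseSD rendering intensity noise SD on the [0,1] scale.
#' @return a [SyntheticCorneaParams-class].
#' @examples
#' p <- corneaParams("subclinical_kc")
#' p@coneDepth
#' @export
corneaParams <- function(group = c("normal", "subclinical_kc", "kc"),
                         anchorMeans = NULL, anchorSDs = NULL,
                         betweenEyeSD = NULL,
                         zoneNoiseSD = .ZONE_NOISE_SD,
                         coneCenter = NA_real_,
                         coneCenterRange = c(-2.5, 0),
                         coneWidth = 1.0,
                         coneDepth = NULL,
                         anteriorRadius = NULL,
                         bowmanEdgeArc = 13 * .WINDOW_CHORD_MM / 10,
                         noiseSD = 0.02) {
  group <- match.arg(group)
  if (is.null(anchorMeans)) anchorMeans <- .REGIONAL_MEANS[[group]]
  if (is.null(anchorSDs)) anchorSDs <- .REGIONAL_SDS[[group]]
  if (is.null(betweenEyeSD)) betweenEyeSD <- rowMeans(anchorSDs)
  if (is.null(coneDepth)) coneDepth <- .CONE_DEPTHS[[group]]
  if (is.null(anteriorRadius)) anteriorRadius <- unname(.ANTERIOR_RADIUS[group])
  new("SyntheticCorneaParams", group = group,
      anchorMeans = anchorMeans, anchorSDs = anchorSDs,
      betweenEyeSD = as.numeric(betweenEyeSD),
      zoneNoiseSD = as.numeric(zoneNoiseSD),
      coneCenter = coneCenter, coneCenterRange = coneCenterRange,
      coneWidth = coneWidth, coneDepth = as.numeric(coneDepth),
      anteriorRadius = anteriorRadius, bowmanEdgeArc = bowmanEdgeArc,
      noiseSD = noiseSD)
}

## Regional analysis windows (mm, arc) and their centres for a given
## Bowman-edge arc distance.
.regionWindows <- function(sEdge) {
  wc <- .WINDOW_CHORD_MM
  list(inferior = c(-sEdge, -sEdge + wc),
       central = c(-wc / 2, wc / 2),
       superior = c(sEdge - wc, sEdge))
}

.regionCenters <- function(sEdge) {
  c(inferior = -(sEdge - .WINDOW_CHORD_MM / 2), central = 0,
    superior = sEdge - .WINDOW_CHORD_MM / 2)
}

## Window mean of f over [a, b] on a fixed quadrature grid.
.windowMean <- function(f, win, npt = 41L) {
  mean(f(seq(win[1L], win[2L], length.out = npt)))
}

## Expected window mean of the unit cone profile exp(-(s-c)^2/(2 sigma^2))
## for each region, averaging over the cone-centre distribution.
.coneWindowMeans <- function(params) {
  wins <- .regionWindows(params@bowmanEdgeArc)
  centers <- if (is.na(params@coneCenter))
    seq(params@coneCenterRange[1L], params@coneCenterRange[2L], length.out = 21L)
  else params@coneCenter
  sig <- params@coneWidth
  vapply(wins, function(w) {
    mean(vapply(centers, function(cc)
      .windowMean(function(s) exp(-(s - cc)^2 / (2 * sig^2)), w), 0))
  }, 0)
}

## Solve the per-layer baseline anchor values so that the regional window
## means of the natural-spline baseline equal the target means after the
## expected cone thinning is subtracted.  The window mean is linear in
## the anchor values, so three basis evaluations give the 3x3 system.
.solveBaselines <- function(params) {
  sEdge <- params@bowmanEdgeArc
  wins <- .regionWindows(sEdge)
  centers <- .regionCenters(sEdge)
  M <- matrix(0, 3L, 3L)
  for (k in 1:3) {
    e <- numeric(3L); e[k] <- 1
    f <- stats::splinefun(centers, e, method = "natural")
    M[, k] <- vapply(wins, .windowMean, 0, f = f)
  }
  g <- .coneWindowMeans(params)
  lapply(seq_along(.LAYERS), function(l) {
    target <- params@anchorMeans[l, ] + params@coneDepth[l] * g
    v <- solve(M, target)
    stats::splinefun(centers, v, method = "natural")
  })
}

#' Draw one ground-truth synthetic cornea
#'
#' Samples a single eye from the group distribution: per-layer thickness
#' along the vertical meridian equals the group baseline profile plus a
#' subject-level additive offset minus a Gaussian cone of localized
#' thinning.  The baseline is the natural spline through regional anchor
#' values solved such that the regional window means (inferior, central,
#' superior) match the group's target means in expectation.
#'
#' @param params a [SyntheticCorneaParams-class].
#' @param seed integer seed; the same seed reproduces the same eye.
#' @param subject optional subject identifier.
#' @return a [GroundTruthCornea-class].
#' @examples
#' gt <- sampleCorneaGeometry(corneaParams("kc"), seed = 42)
#' layerThickness(gt, 0, "epithelium")
#' @export
sampleCorneaGeometry <- function(params, seed, subject = "eye1") {
  stopifnot(is(params, "SyntheticCorneaParams"))
  validObject(params)
  draws <- .withSeed(seed, {
    list(offset = stats::rnorm(3L) * params@betweenEyeSD,
         center = if (is.na(params@coneCenter))
           stats::runif(1L, params@coneCenterRange[1L], params@coneCenterRange[2L])
         else params@coneCenter)
  })
  gt <- new("GroundTruthCornea", subject = subject, group = params@group,
            anteriorRadius = params@anteriorRadius,
            bowmanEdgeArc = params@bowmanEdgeArc,
            baseline = .solveBaselines(params),
            subjectOffset = draws$offset,
            coneCenter = draws$center, coneWidth = params@coneWidth,
            coneDepth = params@coneDepth, seed = as.integer(seed))
  ## positivity over the whole rendered extent
  s <- seq(-params@bowmanEdgeArc - 0.8, params@bowmanEdgeArc + 0.8, by = 0.02)
  for (l in .LAYERS) {
    t <- layerThickness(gt, s, l)
    if (any(t <= 0))
      stop(sprintf("non-positive %s thickness at meridian position %.2f mm",
                   l, s[which.min(t)]))
  }
  gt
}

#' Ground-truth layer thickness
#'
#' Thickness (um) of one layer of a [GroundTruthCornea-class] at meridian
#' (arc) positions `s` (mm, negative = inferior).
#'
#' @param gt a [GroundTruthCornea-class].
#' @param s numeric vector of meridian positions (mm).
#' @param layer `"epithelium"`, `"bowman"` or `"stroma"`.
#' @return numeric vector of thicknesses (um).
#' @export
layerThickness <- function(gt, s, layer = .LAYERS) {
  layer <- match.arg(layer)
  l <- match(layer, .LAYERS)
  gt@baseline[[l]](s) + gt@subjectOffset[l] -
    gt@coneDepth[l] * exp(-(s - gt@coneCenter)^2 / (2 * gt@coneWidth^2))
}

## mean intensity of each tissue compartment on the [0,1] scale
.TISSUE_INT <- c(background = 0.05, epithelium = 0.55, bowman = 0.80,
                 stroma = 0.45, posterior = 0.05)

## Scan rotation (arc position presented at the frame centre) per region:
## peripheral scans are acquired with rotated gaze so the region of
## interest faces the beam; the Bowman edge then sits about 2.16 mm off
## the frame centre, comfortably inside the field of view.
.regionMid <- function(gt, region) {
  off <- gt@bowmanEdgeArc - .WINDOW_CHORD_MM / 2 - 0.05
  switch(region, central = 0, inferior = -off, superior = off)
}

#' Ground-truth boundary rows of a rendered B-scan
#'
#' The exact sub-pixel image rows at which the four interfaces of a
#' ground-truth cornea appear in a rendered scan, accounting for the
#' scan's gaze rotation, Snell refraction at the anterior surface and the
#' optical stretch of sub-surface distances by the refractive index.
#' Used by the renderer itself and as the oracle for segmentation
#' accuracy.
#'
#' @param gt a [GroundTruthCornea-class].
#' @param region scan region.
#' @param geometry a [ScanGeometry-class].
#' @return a list with `rows` (4 x nColumns matrix of sub-pixel rows,
#'   rows named by interface; Bowman-absent columns repeat the
#'   epithelium-Bowman row), `lateral` (column positions, mm) and
#'   `arc` (meridian arc position of each column's surface point, mm).
#' @export
groundTruthBoundaryRows <- function(gt, region = .REGIONS,
                                    geometry = scanGeometry()) {
  region <- match.arg(region)
  R <- gt@anteriorRadius
  n2 <- geometry@refractiveIndex
  sMid <- .regionMid(gt, region)
  z0 <- 0.15
  u <- .columnLateral(geometry)
  if (max(abs(u)) >= R)
    stop("scan width exceeds the anterior curvature radius")
  p <- axialPitchAir(geometry)

  zs <- z0 + R - sqrt(R^2 - u^2)
  sinI <- u / R; cosI <- sqrt(1 - sinI^2)
  eta <- 1 / n2
  sinT <- eta * sinI
  cosT <- sqrt(1 - sinT^2)
  ## refracted unit direction: eta*d + (eta*cosI - cosT)*n_out,
  ## d = (0,1), n_out = (sinI, -cosI)
  tx <- (eta * cosI - cosT) * sinI
  tz <- eta - (eta * cosI - cosT) * cosI

  ## cumulative geometric depth (mm) below the surface per interface
  taper <- function(s) pmin(pmax((gt@bowmanEdgeArc - abs(s)) / 0.05, 0), 1)
  Tfun <- list(
    function(s) rep(0, length(s)),
    function(s) layerThickness(gt, s, "epithelium") / 1000,
    function(s) (layerThickness(gt, s, "epithelium") +
                 layerThickness(gt, s, "bowman") * taper(s)) / 1000,
    function(s) (layerThickness(gt, s, "epithelium") +
                 layerThickness(gt, s, "bowman") * taper(s) +
                 layerThickness(gt, s, "stroma")) / 1000)

  sSurf <- R * asin(sinI) + sMid
  rows <- matrix(NA_real_, 4L, length(u),
                 dimnames = list(.INTERFACES, NULL))
  rows[1L, ] <- zs / p + 0.5
  for (l in 2:4) {
    Tl <- Tfun[[l]]
    xl <- function(s) (R - Tl(s)) * sin((s - sMid) / R)
    zl <- function(s) z0 + R - (R - Tl(s)) * cos((s - sMid) / R)
    f <- function(s) (xl(s) - u) * tz - (zl(s) - zs) * tx
    s0 <- sSurf; f0 <- f(s0)
    s1 <- sSurf + 0.05; f1 <- f(s1)
    for (it in 1:40) {                       # vectorised secant iteration
      den <- f1 - f0
      step <- ifelse(abs(den) > 1e-14, f1 * (s1 - s0) / den, 0)
      s2 <- s1 - step
      s0 <- s1; f0 <- f1
      s1 <- s2; f1 <- f(s1)
      if (max(abs(step)) < 1e-10) break
    }
    sRay <- (xl(s1) - u) * tx + (zl(s1) - zs) * tz
    rows[l, ] <- (zs + n2 * sRay) / p + 0.5
  }
  list(rows = rows, lateral = u, arc = sSurf)
}

#' Render a synthetic UHR-OCT B-scan
#'
#' Draws the layered cornea of a ground-truth eye as a grayscale B-scan:
#' each tissue compartment (background, epithelium, Bowman's layer,
#' stroma, aqueous) gets a fixed mean intensity, boundary pixels are
#' partial-volume blended so interfaces sit at their exact sub-pixel
#' optical rows, additive Gaussian intensity noise is applied and the
#' result quantised to 8-bit levels.  Peripheral scans are rendered with
#' the gaze rotation that brings the respective Bowman's-layer edge into
#' the field of view; the axial position of sub-surface interfaces
#' includes the optical stretch by the refractive index.
#'
#' @param gt a [GroundTruthCornea-class].
#' @param region `"central"`, `"superior"` or `"inferior"`.
#' @param geometry a [ScanGeometry-class].
#' @param seed integer seed for the intensity noise.
#' @param noiseSD noise SD on the [0,1] intensity scale (0 renders a
#'   noiseless scan).
#' @return a [BScan-class].
#' @export
renderBScan <- function(gt, region = .REGIONS, geometry = scanGeometry(),
                        seed = 1L, noiseSD = 0.02) {
  region <- match.arg(region)
  stopifnot(is(gt, "GroundTruthCornea"))
  bt <- groundTruthBoundaryRows(gt, region, geometry)
  nr <- geometry@axialPixels; nc <- geometry@lateralPixels
  lev <- .TISSUE_INT
  img <- matrix(lev[["background"]], nr, nc)
  rowIdx <- seq_len(nr)
  for (l in 1:4) {
    delta <- lev[[l + 1L]] - lev[[l]]
    ## fraction of each pixel lying below interface l
    cov <- pmin(pmax(outer(rowIdx + 0.5, bt$rows[l, ], "-"), 0), 1)
    img <- img + delta * cov
  }
  if (noiseSD > 0)
    img <- img + .withSeed(seed, matrix(stats::rnorm(nr * nc, sd = noiseSD), nr, nc))
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  new("BScan", intensity = img, region = region, geometry = geometry)
}

#' Generate a synthetic cohort
#'
#' Draws whole cohorts of ground-truth eyes with the study's group
#' structure, optionally with per-eye measured vertical profiles (zonal
#' sampling of the ground truth with measurement noise, registered into
#' entire profiles) and/or rendered B-scans of the three regions.
#'
#' @param design named integer vector of eyes per group, e.g.
#'   `c(normal = 5, subclinical_kc = 5, kc = 5)`.
#' @param seed master seed; everything downstream derives from it.
#' @param type `"profiles"` to attach registered [VerticalProfile-class]s
#'   per eye (fast), `"images"` to attach rendered B-scans,
#'   `"geometry"` for ground truth only.
#' @param geometry scan geometry used when rendering.
#' @param paramsList optional named list of [SyntheticCorneaParams-class]
#'   overriding the per-group defaults.
#' @return an object of class `kc_cohort`: a list with `eyes` (each a
#'   list with `gt`, `group`, `subject` and, per `type`, `profiles` or
#'   `scans`), plus the design and seed.
#' @examples
#' coh <- generateCohort(c(normal = 2, kc = 2), seed = 7)
#' sapply(coh$eyes, `[[`, "group")
#' @export
generateCohort <- function(design, seed,
                           type = c("profiles", "images", "geometry"),
                           geometry = scanGeometry(), paramsList = NULL) {
  type <- match.arg(type)
  if (length(design) == 0L) stop("empty cohort design")
  if (any(design < 1L)) stop("all group sizes must be at least 1")
  if (is.null(names(design)) || !all(names(design) %in% .GROUPS))
    stop("design must be named by groups: ", paste(.GROUPS, collapse = ", "))
  if (is.null(paramsList))
    paramsList <- lapply(stats::setNames(nm = names(design)), corneaParams)
  nTot <- sum(design)
  seeds <- .subSeeds(seed, nTot * 5L)
  eyes <- vector("list", nTot)
  i <- 0L
  for (grp in names(design)) {
    for (k in seq_len(design[[grp]])) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", grp, k)
      base <- (i - 1L) * 5L
      gt <- sampleCorneaGeometry(paramsList[[grp]], seeds[base + 1L], sid)
      eye <- list(gt = gt, group = grp, subject = sid)
      if (type == "profiles")
        eye$profiles <- sampleEyeProfiles(gt, paramsList[[grp]], seeds[base + 2L])
      if (type == "images")
        eye$scans <- list(
          inferior = renderBScan(gt, "inferior", geometry, seeds[base + 3L],
                                 paramsList[[grp]]@noiseSD),
          central = renderBScan(gt, "central", geometry, seeds[base + 4L],
                                paramsList[[grp]]@noiseSD),
          superior = renderBScan(gt, "superior", geometry, seeds[base + 5L],
                                 paramsList[[grp]]@noiseSD))
      eyes[[i]] <- eye
    }
  }
  structure(list(eyes = eyes, design = design, seed = seed), class = "kc_cohort")
}

#' Zonally sampled vertical profiles of one ground-truth eye
#'
#' Emulates the measurement protocol directly on the ground truth: for
#' each region and layer, the 10 zone means are the exact window averages
#' of the continuous thickness profile plus independent per-zone
#' measurement noise; the three regions are then registered at the
#' Bowman's-layer edges and apex into one entire vertical profile per
#' layer.
#'
#' @param gt a [GroundTruthCornea-class].
#' @param params the [SyntheticCorneaParams-class] the eye was drawn from
#'   (provides the zone noise SDs).
#' @param seed integer seed for the zone noise.
#' @return named list of three [VerticalProfile-class] objects
#'   (epithelium, bowman, stroma).
#' @export
sampleEyeProfiles <- function(gt, params, seed) {
  w <- .WINDOW_CHORD_MM / 10
  semiSpan <- round(gt@bowmanEdgeArc / w)
  noise <- .withSeed(seed, stats::rnorm(3L * 3L * 10L))
  dim(noise) <- c(10L, 3L, 3L)      # zone x region x layer
  out <- list()
  for (l in seq_along(.LAYERS)) {
    zps <- list()
    for (r in seq_along(.REGIONS)) {
      region <- .REGIONS[r]
      start <- switch(region,
                      inferior = -semiSpan * w,
                      central = -5 * w,
                      superior = semiSpan * w - 10 * w)
      zm <- vapply(1:10, function(k) {
        ss <- seq(start + (k - 1) * w, start + k * w, length.out = 9L)
        mean(layerThickness(gt, ss, .LAYERS[l]))
      }, 0) + noise[, r, l] * params@zoneNoiseSD[l]
      zps[[region]] <- new("ZonalProfile", region = region,
                           layer = .LAYERS[l], zoneMeans = zm,
                           zoneN = rep(100L, 10L),
                           partial = rep(FALSE, 10L), zoneChord = w,
                           aScansPerZone = 100L)
    }
    vp <- registerVerticalProfile(zps$inferior, zps$central, zps$superior,
                                  semiSpanBins = semiSpan)
    vp@subject <- gt@subject; vp@group <- gt@group
    out[[.LAYERS[l]]] <- vp
  }
  out
}
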