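#' Gradient-based boundary cost grid
#'
#' Converts a B-scan into a strictly positive cost grid whose per-column
#' minima sit on intensity transitions of the requested polarity.  The
#' signed vertical gradient is taken by central differences (one-sided at
#' the first and last row); the cost is `max(g) - g + eps`, a monotone
#' decreasing transform of the polarity-matched signed gradient, so
#' minimising path cost maximises summed edge contrast.
#'
#' @param image a [BScan-class] or a numeric intensity matrix.
#' @param polarity `"dark_to_bright"` for interfaces where intensity
#'   increases downward (e.g. air to epithelium), `"bright_to_dark"` for
#'   the reverse (e.g. stroma to aqueous).
#' @return a numeric cost matrix with the dimensions of the image.
#' @seealso [shortestPathBoundary()]
#' @export
gradientCost <- function(image, polarity = c("dark_to_bright", "bright_to_dark")) {
  polarity <- match.arg(polarity)
  m <- if (is(image, "BScan")) image@intensity else image
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("gradientCost needs a matrix with at least 2 rows")
  g <- .signedVerticalGradient(m)
  if (polarity == "bright_to_dark") g <- -g
  max(g) - g + 1e-6
}

.signedVerticalGradient <- function(m) {
  n <- nrow(m)
  g <- matrix(0, n, ncol(m))
  if (n >= 3L) g[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) / 2
  g[1L, ] <- m[2L, ] - m[1L, ]
  g[n, ] <- m[n, ] - m[n - 1L, ]
  g
}

#' Minimum-cost left-to-right boundary path
#'
#' Exact dynamic-programming solution of the shortest-path boundary
#' search: among all row paths r(1..C) with `|r(c+1) - r(c)| <= maxStep`
#' and, optionally, `band[1,c] <= r(c) <= band[2,c]`, returns the one of
#' minimal total cost.  Ties between transitions are broken toward the
#' smaller row change and then toward the upper row, so the output is
#' deterministic.  A parabolic fit of the cost through the three rows
#' around the path refines each column to sub-pixel precision.
#'
#' @param cost numeric cost matrix (rows axial, columns lateral), e.g.
#'   from [gradientCost()]; all entries must be positive and finite.
#' @param band optional 2 x C matrix (or length-2 vector recycled) of
#'   inclusive row bounds per column.
#' @param maxStep integer, maximum row change between adjacent columns.
#' @param interface interface label attached to the returned trace.
#' @param refine logical, apply sub-pixel parabolic refinement.
#' @return a [BoundaryTrace-class]; `position` carries the attribute
#'   `"pathRow"` with the integer DP path and `"totalCost"` with its cost.
#' @export
shortestPathBoundary <- function(cost, band = NULL, maxStep = 2L,
                                 interface = "air_epithelium", refine = TRUE) {
  stopifnot(is.matrix(cost), maxStep >= 0)
  nr <- nrow(cost); nc <- ncol(cost)
  if (!is.null(band)) {
    if (is.null(dim(band))) band <- matrix(band, 2L, nc)
    band[1L, ] <- pmax(1, floor(band[1L, ]))
    band[2L, ] <- pmin(nr, ceiling(band[2L, ]))
    if (any(band[1L, ] > band[2L, ]))
      stop("band is empty in at least one column")
    ## feasibility under the step bound between consecutive columns
    for (cc in seq_len(nc - 1L)) {
      if (band[1L, cc + 1L] > band[2L, cc] + maxStep ||
          band[2L, cc + 1L] < band[1L, cc] - maxStep)
        stop(sprintf("band infeasible under maxStep between columns %d and %d",
                     cc, cc + 1L))
    }
  } else {
    band <- rbind(rep(1L, nc), rep(nr, nc))
  }
  work <- cost
  for (cc in seq_len(nc)) {
    out <- seq_len(nr) < band[1L, cc] | seq_len(nr) > band[2L, cc]
    if (any(out)) work[out, cc] <- Inf
  }
  ## transitions in tie-break preference order: smaller |dr| first, upper row
  ## (negative dr, i.e. coming from the row above) before lower
  drs <- 0L
  if (maxStep > 0L) for (s in seq_len(maxStep)) drs <- c(drs, -s, s)
  D <- matrix(Inf, nr, nc)
  P <- matrix(0L, nr, nc)
  D[, 1L] <- work[, 1L]
  rows <- seq_len(nr)
  for (cc in 2:nc) {
    prev <- D[, cc - 1L]
    best <- rep(Inf, nr); from <- rep(0L, nr)
    for (dr in drs) {
      src <- rows - dr          # path moves by dr: r(c) = r(c-1) + dr
      cand <- rep(Inf, nr)
      ok <- src >= 1L & src <= nr
      cand[ok] <- prev[src[ok]]
      upd <- cand < best        # strict: earlier (preferred) dr wins ties
      if (any(upd)) { best[upd] <- cand[upd]; from[upd] <- dr }
    }
    D[, cc] <- work[, cc] + best
    P[, cc] <- from
  }
  if (!any(is.finite(D[, nc]))) stop("no feasible path under the given band and maxStep")
  path <- integer(nc)
  path[nc] <- which.min(D[, nc])      # ties resolve to the upper row
  for (cc in nc:2) path[cc - 1L] <- path[cc] - P[path[cc], cc]
  pos <- as.numeric(path)
  if (refine) pos <- pos + .parabolicOffset(cost, path)
  structure(
    new("BoundaryTrace", interface = interface,
        position = structure(pos, pathRow = path, totalCost = D[path[nc], nc]),
        valid = rep(TRUE, nc)))
}

## sub-pixel vertex of the parabola through the cost at rows p-1, p, p+1
.parabolicOffset <- function(cost, path) {
  nr <- nrow(cost)
  off <- numeric(length(path))
  inner <- which(path > 1L & path < nr)
  if (length(inner)) {
    y0 <- cost[cbind(path[inner], inner)]
    ym <- cost[cbind(path[inner] - 1L, inner)]
    yp <- cost[cbind(path[inner] + 1L, inner)]
    den <- ym - 2 * y0 + yp
    d <- ifelse(abs(den) > 1e-12, (ym - yp) / (2 * den), 0)
    off[inner] <- pmax(-0.5, pmin(0.5, d))
  }
  off
}

#' Spline initialization of a boundary from sparse seed points
#'
#' Interpolates manually selected seed points (typically 5-6 clicks on
#' the Bowman's layer-stroma interface) with a natural cubic spline,
#' evaluated at every column; beyond the outermost seeds the natural
#' spline extrapolates linearly.
#'
#' @param seedPoints two-column matrix or data.frame of (column, row)
#'   pairs; at least two points with distinct columns.
#' @param nColumns number of columns to evaluate at (1..nColumns).
#' @param interface interface label for the returned trace.
#' @return a [BoundaryTrace-class].
#' @export
splineInitBoundary <- function(seedPoints, nColumns,
                               interface = "bowman_stroma") {
  seedPoints <- as.matrix(seedPoints)
  if (nrow(seedPoints) < 2L)
    stop("at least 2 seed points are required")
  if (anyDuplicated(seedPoints[, 1L]))
    stop("seed points must have distinct columns")
  f <- stats::splinefun(seedPoints[, 1L], seedPoints[, 2L], method = "natural")
  new("BoundaryTrace", interface = interface,
      position = f(seq_len(nColumns)), valid = rep(TRUE, nColumns))
}

#' Segmentation configuration
#'
#' Tunable parameters of [segmentCornea()].  `maxStep` bounds the row
#' change between adjacent columns of a path; `bandHalfWidth` is the
#' half-width (px) of the search band around the spline initialization or
#' nominal offset; nominal layer thicknesses (um) centre the search bands
#' for the deeper interfaces; `validFraction` is the fraction of the
#' maximum edge contrast below which a Bowman-stroma column is flagged
#' invalid (the trace has run off the end of Bowman's layer).
#'
#' @param maxStep,bandHalfWidth integers (px).
#' @param nominalEpithelium,nominalBowman numerics (um).
#' @param validFraction numeric in (0, 1).
#' @return a list of class `kc_segmentation_config`.
#' @export
segmentationConfig <- function(maxStep = 2L, bandHalfWidth = 10L,
                               nominalEpithelium = 50, nominalBowman = 17,
                               validFraction = 0.3) {
  structure(list(maxStep = as.integer(maxStep),
                 bandHalfWidth = as.integer(bandHalfWidth),
                 nominalEpithelium = nominalEpithelium,
                 nominalBowman = nominalBowman,
                 validFraction = validFraction),
            class = "kc_segmentation_config")
}

#' Segment the four corneal interfaces of a B-scan
#'
#' The air-epithelium surface is found by an unconstrained shortest path
#' on the dark-to-bright cost; the epithelium-Bowman interface by a
#' banded search below it (dark to bright: Bowman's layer is
#' hyper-reflective); the Bowman-stroma interface (bright to dark) inside
#' a band around the spline interpolation of the seed points when given,
#' otherwise around the epithelium-Bowman trace offset by a nominal
#' Bowman thickness; and the posterior surface by a bright-to-dark search
#' well below the Bowman-stroma trace.  Bowman-stroma columns whose edge
#' contrast falls below `validFraction` of the trace's maximum are marked
#' invalid: this is what terminates the trace at the peripheral edge of
#' Bowman's layer.  Manual corrections are applied last; any ordering
#' violations are clipped and the columns flagged.
#'
#' @param image a [BScan-class].
#' @param config a [segmentationConfig()] list.
#' @param seeds optional (column, row) seed points for the Bowman-stroma
#'   interface, as for [splineInitBoundary()].
#' @param corrections optional list of corrections, each a list with
#'   elements `interface`, `columns` (integer vector) and `offset` (rows
#'   to add) or `rows` (absolute replacement positions).
#' @return a [BoundarySet-class]; slot `clipped` lists columns where the
#'   ordering invariant had to be enforced.
#' @examples
#' gt <- sampleCorneaGeometry(corneaParams("normal"), seed = 1)
#' g  <- scanGeometry(342L, 512L)
#' b  <- renderBScan(gt, "central", g, seed = 1, noiseSD = 0)
#' bs <- segmentCornea(b)
#' @export
segmentCornea <- function(image, config = segmentationConfig(),
                          seeds = NULL, corrections = NULL) {
  stopifnot(is(image, "BScan"))
  geom <- image@geometry
  nr <- nrow(image@intensity); nc <- ncol(image@intensity)
  costDB <- gradientCost(image, "dark_to_bright")
  costBD <- gradientCost(image, "bright_to_dark")
  bw <- max(config$bandHalfWidth,
            ceiling(.opticalRows(15, geom)))  # at least ~15 um of slack

  airEpi <- shortestPathBoundary(costDB, maxStep = config$maxStep,
                                 interface = "air_epithelium")
  if (max(attr(airEpi@position, "pathRow")) <= 2L ||
      stats::sd(image@intensity) < 1e-8)
    stop("image without detectable anterior surface")

  epiRows <- .opticalRows(config$nominalEpithelium, geom)
  bw2 <- max(config$bandHalfWidth, ceiling(.opticalRows(20, geom)))
  ## the lower band edge stays clear of the (stronger) anterior surface edge
  band2 <- rbind(airEpi@position + pmax(epiRows - bw2, 3),
                 airEpi@position + epiRows + bw2)
  epiBow <- shortestPathBoundary(costDB, band2, config$maxStep,
                                 "epithelium_bowman")

  bowRows <- .opticalRows(config$nominalBowman, geom)
  if (!is.null(seeds)) {
    init <- splineInitBoundary(seeds, nc)
    band3 <- rbind(init@position - config$bandHalfWidth,
                   init@position + config$bandHalfWidth)
  } else {
    band3 <- rbind(epiBow@position + bowRows - bw,
                   epiBow@position + bowRows + bw)
  }
  band3[1L, ] <- pmax(band3[1L, ], epiBow@position + 1)
  band3[2L, ] <- pmax(band3[2L, ], band3[1L, ])   # spline may extrapolate above
  bowStr <- shortestPathBoundary(costBD, band3, config$maxStep,
                                 "bowman_stroma")

  margin <- .opticalRows(120, geom)            # skip the Bowman-stroma edge
  band4 <- rbind(bowStr@position + margin, rep(nr, nc))
  stromaPost <- shortestPathBoundary(costBD, band4, config$maxStep,
                                     "stroma_posterior")

  ## validity from edge contrast along the refined paths: a trace is
  ## meaningful only where the expected intensity transition is present
  ## (the Bowman interfaces lose contrast beyond the layer's edge; any
  ## path loses contrast where the bounded step cannot follow a steep
  ## peripheral interface)
  g <- .signedVerticalGradient(image@intensity)
  contrastValid <- function(trace, sign) {
    s <- sign * g[cbind(attr(trace@position, "pathRow"), seq_len(nc))]
    trace@valid <- s >= config$validFraction * max(s)
    trace@position[!trace@valid] <- NA_real_
    trace
  }
  airEpi <- contrastValid(airEpi, 1)
  epiBow <- contrastValid(epiBow, 1)
  bowStr <- contrastValid(bowStr, -1)
  stromaPost <- contrastValid(stromaPost, -1)
  ## without a surface the deeper positions are meaningless; posterior
  ## columns clipped by the frame bottom are invalid too
  postRow <- attr(stromaPost@position, "pathRow")
  stromaPost@valid <- stromaPost@valid & postRow < nr - 1L
  for (nm in c("epiBow", "bowStr", "stromaPost")) {
    tr <- get(nm)
    tr@valid <- tr@valid & airEpi@valid
    tr@position[!tr@valid] <- NA_real_
    assign(nm, tr)
  }

  traces <- list(air_epithelium = airEpi, epithelium_bowman = epiBow,
                 bowman_stroma = bowStr, stroma_posterior = stromaPost)

  if (!is.null(corrections)) {
    for (corr in corrections) {
      iface <- corr$interface
      if (!iface %in% .INTERFACES) stop("unknown interface in correction: ", iface)
      cols <- corr$columns
      tr <- traces[[iface]]
      if (!is.null(corr$offset)) tr@position[cols] <- tr@position[cols] + corr$offset
      else tr@position[cols] <- corr$rows
      tr@valid[cols] <- is.finite(tr@position[cols])
      traces[[iface]] <- tr
    }
  }

  ## enforce anterior-to-posterior ordering by clipping, flag the columns
  clipped <- integer(0)
  for (k in 1:3) {
    a <- traces[[k]]; b <- traces[[k + 1L]]
    both <- a@valid & b@valid
    viol <- which(both & b@position < a@position)
    if (length(viol)) {
      b@position[viol] <- a@position[viol]
      traces[[k + 1L]] <- b
      clipped <- union(clipped, viol)
    }
  }
  names(traces) <- .INTERFACES
  new("BoundarySet", traces = traces, region = image@region,
      geometry = geom, clipped = sort(clipped))
}
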