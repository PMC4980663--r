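#' Locate the Bowman's-layer edges of a segmented B-scan
#'
#' Finds the termini of the Bowman-stroma trace: the outermost columns of
#' its longest valid run, after closing gaps up to `gapTolerance`
#' columns (single-column segmentation dropouts must not split the run).
#' A terminus lying at the image border is the trace running out of the
#' field of view, not a true edge, and is not reported; a central scan
#' whose Bowman's layer crosses the whole image therefore returns an
#' empty result.  Peripheral scans must show their edge, so a missing
#' in-view terminus is an error.
#'
#' @param boundaries a [BoundarySet-class].
#' @param gapTolerance integer, largest invalid gap (columns) closed when
#'   tracing the valid run.
#' @return named integer vector of edge columns; names are
#'   `"inferior"` and/or `"superior"` (columns run inferior to superior).
#' @export
detectBowmanEdges <- function(boundaries, gapTolerance = 5L) {
  stopifnot(is(boundaries, "BoundarySet"))
  v <- boundaries@traces[["bowman_stroma"]]@valid
  nc <- length(v)
  if (!any(v)) stop("Bowman-stroma trace has no valid columns")
  idx <- which(v)
  ## merge runs separated by <= gapTolerance invalid columns
  breaks <- which(diff(idx) > gapTolerance + 1L)
  starts <- c(idx[1L], idx[breaks + 1L])
  ends <- c(idx[breaks], idx[length(idx)])
  runLen <- ends - starts + 1L
  best <- which.max(runLen)
  lo <- starts[best]; hi <- ends[best]
  border <- 3L
  edges <- integer(0)
  if (lo > border) edges <- c(edges, inferior = lo)
  if (hi < nc - border + 1L) edges <- c(edges, superior = hi)
  region <- boundaries@region
  if (region == "inferior" && !("inferior" %in% names(edges)))
    stop("inferior Bowman's layer edge not in view")
  if (region == "superior" && !("superior" %in% names(edges)))
    stop("superior Bowman's layer edge not in view")
  edges
}

#' Average an A-scan thickness profile into 10 zones
#'
#' Selects the region's analysis window (for central scans the window is
#' centred on the apex A-scan; for peripheral scans it starts at the
#' Bowman's-layer edge and extends toward the corneal centre) and takes
#' the block mean of each tenth of the window, ordered inferior to
#' superior.  Invalid A-scans are excluded from their block mean and
#' counted; a zone with fewer than 60 percent valid A-scans is flagged
#' partial.
#'
#' @param profile an [AScanThicknessProfile-class].
#' @param edges named edge columns from [detectBowmanEdges()] (required
#'   for peripheral regions).
#' @param apexCol apex column from [apexColumn()] (required for central).
#' @return a [ZonalProfile-class].
#' @export
zonalAverage <- function(profile, edges = NULL, apexCol = NULL) {
  stopifnot(is(profile, "AScanThicknessProfile"))
  geom <- profile@geometry
  W <- windowAScans(geom)
  nz <- .ZONES_PER_REGION
  per <- W %/% nz
  nc <- length(profile@thickness)
  region <- profile@region
  cols <- switch(region,
    central = {
      if (is.null(apexCol)) stop("central window needs the apex column")
      seq(apexCol - W %/% 2 + 1L, length.out = W)
    },
    inferior = {
      if (is.null(edges) || !("inferior" %in% names(edges)))
        stop("inferior window needs the inferior Bowman edge")
      seq(edges[["inferior"]], length.out = W)
    },
    superior = {
      if (is.null(edges) || !("superior" %in% names(edges)))
        stop("superior window needs the superior Bowman edge")
      seq(edges[["superior"]] - W + 1L, length.out = W)
    })
  if (cols[1L] < 1L || cols[W] > nc)
    stop(sprintf("analysis window [%d, %d] truncated by the image border",
                 cols[1L], cols[W]))
  th <- profile@thickness[cols]
  ok <- profile@valid[cols]
  zone <- rep(seq_len(nz), each = per)
  zm <- vapply(seq_len(nz), function(z) {
    i <- zone == z & ok
    if (any(i)) mean(th[i]) else NA_real_
  }, 0)
  zn <- vapply(seq_len(nz), function(z) sum(zone == z & ok), 0L)
  new("ZonalProfile", region = region, layer = profile@layer,
      zoneMeans = zm, zoneN = zn, partial = zn < 0.6 * per,
      zoneChord = per * lateralPitch(geom), aScansPerZone = as.integer(per))
}

#' Register three regional profiles into one entire vertical profile
#'
#' Places the 10 zones of the inferior, central and superior regions onto
#' the common apex-anchored bin axis: central zones occupy bins -5..4,
#' peripheral zones are anchored at their Bowman's-layer edge
#' (`semiSpanBins` bins from the apex, about 5.5 mm with the default
#' 11-mm edge-to-edge cornea).  Bins covered by two regions are averaged
#' with equal weight; partial zones are excluded from the average, and
#' bins left without a usable zone are interpolated but flagged invalid.
#'
#' @param inferior,central,superior [ZonalProfile-class] objects of one
#'   layer.
#' @param semiSpanBins integer, bins between apex and either Bowman edge.
#' @return a [VerticalProfile-class] spanning bins
#'   `-semiSpanBins .. semiSpanBins - 1` (26 bins by default).
#' @export
registerVerticalProfile <- function(inferior, central, superior,
                                    semiSpanBins = 13L) {
  zps <- list(inferior = inferior, central = central, superior = superior)
  for (r in names(zps)) {
    if (is.null(zps[[r]]) || !is(zps[[r]], "ZonalProfile"))
      stop("missing ", r, " regional profile")
    if (zps[[r]]@region != r)
      stop(sprintf("profile passed as %s is labelled %s", r, zps[[r]]@region))
  }
  layer <- unique(vapply(zps, slot, "", "layer"))
  if (length(layer) != 1L) stop("regional profiles are of different layers")
  S <- as.integer(semiSpanBins)
  binFirst <- list(inferior = -S, central = -5L, superior = S - 10L)
  gapInf <- (-5L) - (binFirst$inferior + 10L)   # bins between windows
  gapSup <- binFirst$superior - 5L
  if (gapInf > 1L || gapSup > 1L)
    stop("inconsistent anchors: gap between regional windows exceeds 1 bin")
  bins <- seq(-S, S - 1L)
  nb <- length(bins)
  acc <- num <- cov <- numeric(nb)
  for (r in names(zps)) {
    zp <- zps[[r]]
    at <- match(binFirst[[r]] + 0:9, bins)
    cov[at] <- cov[at] + 1
    use <- !zp@partial & is.finite(zp@zoneMeans)
    acc[at[use]] <- acc[at[use]] + zp@zoneMeans[use]
    num[at[use]] <- num[at[use]] + 1
  }
  vals <- ifelse(num > 0, acc / pmax(num, 1), NA_real_)
  valid <- num > 0
  if (any(!valid)) {                 # interpolate flagged gaps
    ii <- which(valid)
    vals[!valid] <- stats::approx(bins[ii], vals[ii], xout = bins[!valid],
                                  rule = 2)$y
  }
  new("VerticalProfile", layer = layer, binIndex = as.integer(bins),
      values = vals, nRegions = as.integer(pmax(cov, 1)),
      valid = valid, binWidth = zps$central@zoneChord)
}

#' Chord positions of vertical-profile bins
#'
#' Centre (or edge) chord positions of each bin of a
#' [VerticalProfile-class], in mm from the apex (negative inferior).
#'
#' @param profile a [VerticalProfile-class].
#' @param where `"center"` or `"lower"` edge.
#' @return numeric vector (mm).
#' @export
binChord <- function(profile, where = c("center", "lower")) {
  where <- match.arg(where)
  off <- if (where == "center") 0.5 else 0
  (profile@binIndex + off) * profile@binWidth
}

#' Plot an entire vertical thickness profile
#'
#' Thickness against chord position along the vertical meridian, in the
#' style of the usual zonal profile panels.
#'
#' @param profile a [VerticalProfile-class].
#' @param add logical, add to an existing plot.
#' @param ... passed to [graphics::plot()]/[graphics::lines()].
#' @return invisibly, the plotted coordinates.
#' @export
plotVerticalProfile <- function(profile, add = FALSE, ...) {
  x <- binChord(profile)
  y <- profile@values
  if (!add)
    graphics::plot(x, y, type = "b", xlab = "chord from apex (mm)",
                   ylab = sprintf("%s thickness (µm)", profile@layer), ...)
  else graphics::lines(x, y, type = "b", ...)
  invisible(data.frame(chord_mm = x, thickness_um = y))
}
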