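## Independent oracles and small fixture builders shared by the tests.

## exhaustive minimum-cost path over all feasible row paths (reference
## implementation for the dynamic-programming search)
bruteForcePathCost <- function(cost, maxStep = 1L, band = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.null(band)) band <- rbind(rep(1L, nc), rep(nr, nc))
  best <- Inf
  recurse <- function(col, row, acc) {
    if (acc >= best) return(invisible(NULL))
    if (col == nc) { best <<- min(best, acc); return(invisible(NULL)) }
    for (r2 in seq(max(band[1L, col + 1L], row - maxStep),
                   min(band[2L, col + 1L], row + maxStep))) {
      if (r2 >= 1L && r2 <= nr) recurse(col + 1L, r2, acc + cost[r2, col + 1L])
    }
    invisible(NULL)
  }
  for (r in seq(band[1L, 1L], band[2L, 1L])) recurse(1L, r, cost[r, 1L])
  best
}

## concordance-probability AUC with ties counted one half
concordanceAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

## quick VerticalProfile on a symmetric bin axis
makeProfile <- function(values, layer = "epithelium", binWidth = 0.423,
                        valid = NULL) {
  n <- length(values)
  stopifnot(n %% 2 == 0)
  if (is.null(valid)) valid <- rep(TRUE, n)
  new("VerticalProfile", layer = layer,
      binIndex = as.integer(seq(-n / 2, n / 2 - 1)),
      values = as.numeric(values), nRegions = rep(1L, n),
      valid = valid, binWidth = binWidth)
}

makePattern <- function(values, layer = "epithelium", binWidth = 0.423, n = 5L) {
  m <- length(values)
  new("NormalPattern", layer = layer,
      binIndex = as.integer(seq(-m / 2, m / 2 - 1)),
      mean = as.numeric(values), n = n, binWidth = binWidth)
}

## ZonalProfile builder for registration tests
makeZonal <- function(region, values, layer = "epithelium",
                      partial = rep(FALSE, 10), zoneChord = 0.423) {
  new("ZonalProfile", region = region, layer = layer,
      zoneMeans = as.numeric(values), zoneN = rep(100L, 10L),
      partial = partial, zoneChord = zoneChord, aScansPerZone = 100L)
}

## memoised noiseless rendered eye (shared by segmentation/pipeline tests)
.fixtures <- new.env(parent = emptyenv())
renderedEye <- function(group = "normal", seed = 3) {
  key <- paste(group, seed)
  if (is.null(.fixtures[[key]])) {
    gt <- sampleCorneaGeometry(corneaParams(group), seed = seed)
    geom <- scanGeometry(342L, 512L)
    scans <- lapply(stats::setNames(nm = c("inferior", "central", "superior")),
                    function(r) renderBScan(gt, r, geom, seed = seed, noiseSD = 0))
    .fixtures[[key]] <- list(gt = gt, geom = geom, scans = scans)
  }
  .fixtures[[key]]
}

## columns of a scan that fall inside the regional analysis window
## (every region's window straddles its own frame centre to within a
## fraction of a zone, so a symmetric chord bound suffices)
windowColumns <- function(geom) {
  u <- (seq_len(geom@lateralPixels) - (geom@lateralPixels + 1) / 2) *
    lateralPitch(geom)
  abs(u) <= windowChord(geom) / 2 + 0.1
}

## the exact analysis-window columns an analyzeEye() run used for a region
analysisColumns <- function(res, region, geom) {
  W <- windowAScans(geom)
  cols <- switch(region,
    central = seq(res$apexCol - W %/% 2 + 1L, length.out = W),
    inferior = seq(res$edges$inferior[["inferior"]], length.out = W),
    superior = seq(res$edges$superior[["superior"]] - W + 1L, length.out = W))
  mask <- rep(FALSE, geom@lateralPixels)
  mask[cols[cols >= 1L & cols <= geom@lateralPixels]] <- TRUE
  mask
}
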