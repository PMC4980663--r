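#' Pixel pitches and zonal chord arithmetic
#'
#' Helper accessors translating a [ScanGeometry-class] into physical
#' sampling quantities.  `lateralPitch` is the chord spanned by one
#' A-scan, `axialPitchAir` the depth of one pixel in air; `zoneChord` is
#' the chord of one 100-A-scan-equivalent zone, `windowChord` the chord
#' of the 10-zone analysis window, and `windowAScans` the number of
#' A-scans in that window for the given sampling (always a multiple of
#' 10).  With the default geometry the window is exactly 1,000 A-scans
#' (4.23 mm) and a zone 100 A-scans (0.42 mm).
#'
#' @param geometry a [ScanGeometry-class].
#' @return a single numeric (mm per pixel, mm, or a count).
#' @examples
#' g <- scanGeometry()
#' round(windowChord(g), 2)  # 4.23
#' round(zoneChord(g), 2)    # 0.42
#' @export
lateralPitch <- function(geometry) geometry@lateralExtent / geometry@lateralPixels

#' @rdname lateralPitch
#' @export
axialPitchAir <- function(geometry) geometry@axialExtentAir / geometry@axialPixels

## The analysis window is defined physically (the chord that 1,000 A-scans
## of the reference sampling cover) so that down-sampled geometries keep
## the same zonal arithmetic.
.WINDOW_CHORD_MM <- 1000 * 8.66 / 2048

#' @rdname lateralPitch
#' @export
windowChord <- function(geometry) .WINDOW_CHORD_MM

#' @rdname lateralPitch
#' @export
zoneChord <- function(geometry) .WINDOW_CHORD_MM / 10

#' @rdname lateralPitch
#' @export
windowAScans <- function(geometry) {
  n <- round(.WINDOW_CHORD_MM / lateralPitch(geometry) / 10) * 10
  as.integer(max(n, 10L))
}

#' Zone chord bounds relative to the apex
#'
#' Distance from the apex to the inner and outer chord boundary of the
#' k-th zone counted outward from the apex (the labelling used when
#' reporting, e.g., "central 1.69 to 2.11 mm" for the 4th zone out).
#'
#' @param k integer zone number counted outward from the apex (1-based).
#' @param geometry a [ScanGeometry-class].
#' @return numeric matrix with columns `inner` and `outer` (mm).
#' @examples
#' round(zoneChordBounds(3:5), 2)
#' @export
zoneChordBounds <- function(k, geometry = scanGeometry()) {
  w <- zoneChord(geometry)
  cbind(inner = (k - 1) * w, outer = k * w)
}

## lateral position (mm) of each column, centred on the scan axis
.columnLateral <- function(geometry) {
  (seq_len(geometry@lateralPixels) - (geometry@lateralPixels + 1) / 2) *
    lateralPitch(geometry)
}

## optical rows spanned by a tissue thickness of t micrometres
.opticalRows <- function(t_um, geometry) {
  t_um * 1e-3 * geometry@refractiveIndex / axialPitchAir(geometry)
}

## Run a block of code with a private, restorable RNG stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## derive a stream of sub-seeds (< 2^31) from a master seed
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
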