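## strict numeric conversion: error names the offending cell
.numericColumn <- function(x, col, file) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "NA")
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                 file, x[bad[1L]], col, bad[1L]))
  v
}

#' Read and write B-scan images
#'
#' Single-channel TIFF or PNG (chosen by extension), intensities on
#' [0, 1].
#'
#' @param scan a [BScan-class].
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param region,geometry metadata attached on reading.
#' @return `readBScan` returns a [BScan-class]; `writeBScan` the path,
#'   invisibly.
#' @export
writeBScan <- function(scan, path) {
  stopifnot(is(scan, "BScan"))
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(scan@intensity, 0), 1)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop("unsupported image extension: .", ext))
  invisible(path)
}

#' @rdname writeBScan
#' @export
readBScan <- function(path, region = "central", geometry = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (is.null(geometry))
    geometry <- scanGeometry(axialPixels = nrow(img), lateralPixels = ncol(img))
  new("BScan", intensity = img, region = region, geometry = geometry)
}

#' Read and write boundary sets as CSV
#'
#' Columns: `column`, `interface`, `row`, `valid`.
#'
#' @param boundaries a [BoundarySet-class].
#' @param path CSV path.
#' @param region,geometry metadata attached on reading.
#' @return `readBoundarySet` a [BoundarySet-class]; the writer its path,
#'   invisibly.
#' @export
writeBoundarySet <- function(boundaries, path) {
  stopifnot(is(boundaries, "BoundarySet"))
  rows <- do.call(rbind, lapply(.INTERFACES, function(i) {
    tr <- boundaries@traces[[i]]
    data.frame(column = seq_along(tr@position), interface = i,
               row = tr@position, valid = tr@valid)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBoundarySet
#' @export
readBoundarySet <- function(path, region = "central", geometry = scanGeometry()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("column", "interface", "row", "valid")
  if (!all(need %in% names(d)))
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  d$row <- .numericColumn(as.character(d$row), "row", path)
  traces <- lapply(.INTERFACES, function(i) {
    di <- d[d$interface == i, ]
    di <- di[order(di$column), ]
    new("BoundaryTrace", interface = i, position = di$row,
        valid = as.logical(di$valid))
  })
  names(traces) <- .INTERFACES
  new("BoundarySet", traces = traces, region = region, geometry = geometry,
      clipped = integer(0))
}

#' Read and write vertical profiles as CSV
#'
#' Columns: `subject`, `group`, `layer`, `bin_index`, `chord_mm`,
#' `thickness_um`, `n_regions`, `valid`.  A file may hold several
#' subjects and layers; the reader returns a list of
#' [VerticalProfile-class] objects.
#'
#' @param profiles a [VerticalProfile-class] or list of them.
#' @param path CSV path.
#' @return the reader a list of profiles; the writer its path, invisibly.
#' @export
writeVerticalProfiles <- function(profiles, path) {
  if (is(profiles, "VerticalProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject = p@subject, group = p@group, layer = p@layer,
               bin_index = p@binIndex, chord_mm = binChord(p),
               thickness_um = p@values, n_regions = p@nRegions,
               valid = p@valid)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVerticalProfiles
#' @export
readVerticalProfiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "layer", "bin_index", "chord_mm", "thickness_um",
            "n_regions", "valid")
  if (!all(need %in% names(d)))
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  d$thickness_um <- .numericColumn(as.character(d$thickness_um),
                                   "thickness_um", path)
  keys <- unique(d[, c("subject", "layer")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    di <- d[d$subject == keys$subject[i] & d$layer == keys$layer[i], ]
    di <- di[order(di$bin_index), ]
    w <- if (nrow(di) > 1L) diff(di$chord_mm)[1L] else .WINDOW_CHORD_MM / 10
    new("VerticalProfile", layer = keys$layer[i],
        binIndex = as.integer(di$bin_index), values = di$thickness_um,
        nRegions = as.integer(di$n_regions), valid = as.logical(di$valid),
        binWidth = w, subject = as.character(keys$subject[i]),
        group = if ("group" %in% names(di)) as.character(di$group[1L])
                else NA_character_)
  })
  out
}

#' Serialize a discriminant model to JSON
#'
#' @param model a [DiscriminantModel-class].
#' @param path JSON path.
#' @return the reader a [DiscriminantModel-class]; the writer its path,
#'   invisibly.
#' @export
writeDiscriminantModel <- function(model, path) {
  stopifnot(is(model, "DiscriminantModel"))
  obj <- list(features = model@features,
              coefficients = as.numeric(model@coefficients),
              intercept = model@intercept, lambda = model@lambda,
              f_enter = model@fEnter, groups = model@groups,
              normal_group = model@normalGroup, empty = model@empty)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDiscriminantModel
#' @export
readDiscriminantModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DiscriminantModel", features = as.character(o$features),
      coefficients = stats::setNames(as.numeric(o$coefficients),
                                     as.character(o$features)),
      intercept = o$intercept, lambda = as.numeric(o$lambda),
      fEnter = o$f_enter, groups = as.character(o$groups),
      normalGroup = o$normal_group, empty = isTRUE(o$empty))
}

#' Write an ROC curve as CSV
#'
#' @param roc an [ROCResult-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeROCTable <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc@thresholds,
                              sensitivity = roc@sensitivity,
                              specificity = roc@specificity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export ground truth as CSV
#'
#' One row per meridian sample per layer: `subject`, `group`,
#' `chord_mm`, `layer`, `thickness_um`.
#'
#' @param gt a [GroundTruthCornea-class].
#' @param path CSV path.
#' @param step sampling step (mm).
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(gt, path, step = 0.1) {
  s <- seq(-gt@bowmanEdgeArc, gt@bowmanEdgeArc, by = step)
  rows <- do.call(rbind, lapply(.LAYERS, function(l)
    data.frame(subject = gt@subject, group = gt@group, chord_mm = s,
               layer = l, thickness_um = layerThickness(gt, s, l))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

.CONFIG_DEFAULTS <- list(
  geometry = list(axial_pixels = 1365L, lateral_pixels = 2048L,
                  axial_extent_air = 2.02, lateral_extent = 8.66,
                  refractive_index = 1.389),
  segmentation = list(max_step = 2L, band_half_width = 10L,
                      nominal_epithelium = 50, nominal_bowman = 17,
                      valid_fraction = 0.3),
  profile = list(semi_span_bins = 13L, gap_tolerance = 5L),
  stats = list(f_enter = 3.84, seed = 1L))

#' Pipeline configuration
#'
#' Reads a YAML or JSON configuration and validates it against the
#' package defaults; unknown keys are rejected so typos cannot silently
#' fall back to defaults.  `pipelineConfig()` returns the defaults,
#' optionally overridden.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @param ... named blocks overriding defaults, e.g.
#'   `segmentation = list(max_step = 3)`.
#' @return a nested list with blocks `geometry`, `segmentation`,
#'   `profile`, `stats`.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  cfg <- .CONFIG_DEFAULTS
  for (blk in names(over)) {
    if (!blk %in% names(cfg)) stop("unknown configuration block: ", blk)
    for (key in names(over[[blk]])) {
      if (!key %in% names(cfg[[blk]]))
        stop(sprintf("unknown configuration key: %s.%s", blk, key))
      cfg[[blk]][[key]] <- over[[blk]][[key]]
    }
  }
  cfg
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: .", ext))
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @export
configGeometry <- function(config) {
  g <- config$geometry
  scanGeometry(g$axial_pixels, g$lateral_pixels, g$axial_extent_air,
               g$lateral_extent, g$refractive_index)
}

#' @rdname pipelineConfig
#' @export
configSegmentation <- function(config) {
  s <- config$segmentation
  segmentationConfig(s$max_step, s$band_half_width, s$nominal_epithelium,
                     s$nominal_bowman, s$valid_fraction)
}

#' Read and write normal patterns as CSV
#'
#' Columns: `layer`, `bin_index`, `mean_um`, `n`.
#'
#' @param pattern a [NormalPattern-class], or a named list of them.
#' @param path CSV path.
#' @return the reader a named list of patterns (by layer); the writer
#'   its path, invisibly.
#' @export
writeNormalPatterns <- function(pattern, path) {
  if (is(pattern, "NormalPattern")) pattern <- list(pattern)
  rows <- do.call(rbind, lapply(pattern, function(p)
    data.frame(layer = p@layer, bin_index = p@binIndex, mean_um = p@mean,
               n = p@n, bin_width = p@binWidth)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalPatterns
#' @export
readNormalPatterns <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$mean_um <- .numericColumn(as.character(d$mean_um), "mean_um", path)
  out <- lapply(split(d, d$layer), function(di) {
    di <- di[order(di$bin_index), ]
    new("NormalPattern", layer = di$layer[1L],
        binIndex = as.integer(di$bin_index), mean = di$mean_um,
        n = as.integer(di$n[1L]), binWidth = di$bin_width[1L])
  })
  out[intersect(.LAYERS, names(out))]
}

#' Read and write index tables as CSV
#'
#' One row per eye: `subject`, `group` and the twelve indices.
#'
#' @param indexTable data.frame from [cohortIndexTable()].
#' @param path CSV path.
#' @return the reader the validated data.frame; the writer its path,
#'   invisibly.
#' @export
writeIndexTable <- function(indexTable, path) {
  utils::write.csv(indexTable, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIndexTable
#' @export
readIndexTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in intersect(.INDEX_NAMES, names(d)))
    d[[v]] <- .numericColumn(as.character(d[[v]]), v, path)
  d
}
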