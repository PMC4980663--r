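#' Build the normal reference pattern
#'
#' Per-bin arithmetic mean of the vertical profiles of a reference cohort
#' of normal eyes (the "pattern average" the PSD indices score against).
#' Bins excluded in some subjects are averaged over the subjects in which
#' they are valid.
#'
#' @param profiles list of [VerticalProfile-class] objects of one layer
#'   on one bin axis.
#' @return a [NormalPattern-class].
#' @export
buildNormalPattern <- function(profiles) {
  if (length(profiles) == 0L) stop("empty reference cohort")
  layer <- unique(vapply(profiles, slot, "", "layer"))
  if (length(layer) != 1L) stop("profiles are of different layers")
  axis <- profiles[[1L]]@binIndex
  for (p in profiles)
    if (!identical(p@binIndex, axis))
      stop("profiles are on mismatched bin axes")
  vals <- vapply(profiles, function(p) {
    v <- p@values; v[!p@valid] <- NA_real_; v
  }, numeric(length(axis)))
  vals <- matrix(vals, nrow = length(axis))
  m <- rowMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  new("NormalPattern", layer = layer, binIndex = axis, mean = m,
      n = length(profiles), binWidth = profiles[[1L]]@binWidth)
}

## valid bins of the inferior (bin centre < 0) and superior halves
.halves <- function(profile) {
  ctr <- binChord(profile)
  ok <- profile@valid & is.finite(profile@values)
  list(inferior = profile@values[ok & ctr < 0],
       superior = profile@values[ok & ctr > 0])
}

#' Ectasia indices of a vertical profile
#'
#' `EI  = 100 * min(inferior half) / mean(superior half)` and
#' `EI_MAX = 100 * min(inferior half) / max(superior half)`: the halves
#' are the valid bins below and above the apex of the entire registered
#' profile.  Low values indicate localized inferior or central thinning.
#'
#' @param profile a [VerticalProfile-class].
#' @return named numeric: `EI`, `EI_MAX` (percent).
#' @export
ectasiaIndices <- function(profile) {
  h <- .halves(profile)
  if (length(h$inferior) < 2L || length(h$superior) < 2L)
    stop("ectasia indices need at least 2 valid bins on each side of the apex")
  mn <- min(h$inferior)
  c(EI = 100 * mn / mean(h$superior), EI_MAX = 100 * mn / max(h$superior))
}

#' Profile variation
#'
#' Root mean square of the valid zonal thicknesses about the subject's
#' own profile mean (um): the within-subject irregularity of the layer.
#'
#' @param profile a [VerticalProfile-class].
#' @return numeric (um).
#' @export
profileVariation <- function(profile) {
  v <- profile@values[profile@valid & is.finite(profile@values)]
  if (length(v) < 2L) stop("profile variation needs at least 2 valid bins")
  sqrt(mean((v - mean(v))^2))
}

#' Pattern standard deviation
#'
#' Root mean square of the differences between a subject's zonal
#' thicknesses and the normal-cohort pattern average, over the bins
#' valid in both (um): the deviation of the profile from the normal
#' shape.
#'
#' @param profile a [VerticalProfile-class].
#' @param pattern a [NormalPattern-class] of the same layer and bin axis.
#' @return numeric (um).
#' @export
patternSD <- function(profile, pattern) {
  stopifnot(is(pattern, "NormalPattern"))
  if (profile@layer != pattern@layer)
    stop("profile and pattern are of different layers")
  if (!identical(profile@binIndex, pattern@binIndex))
    stop("profile and pattern are on mismatched bin axes")
  ok <- profile@valid & is.finite(profile@values) & is.finite(pattern@mean)
  if (!any(ok)) stop("no shared valid bins")
  sqrt(mean((profile@values[ok] - pattern@mean[ok])^2))
}

#' Compute the twelve diagnostic indices of one eye
#'
#' Applies the ectasia, variation and pattern-deviation indices to the
#' epithelial, Bowman's-layer and stromal vertical profiles of one
#' subject.  A missing per-layer pattern leaves that layer's PSD unset
#' (flagged); any other per-layer failure propagates with the layer
#' named.
#'
#' @param epithelium,bowman,stroma [VerticalProfile-class] objects of one
#'   subject.
#' @param patterns named list of [NormalPattern-class] objects (any of
#'   `epithelium`, `bowman`, `stroma`).
#' @return an [IndexSet-class].
#' @examples
#' coh <- generateCohort(c(normal = 3), seed = 1)
#' pat <- lapply(setNames(nm = c("epithelium", "bowman", "stroma")),
#'               function(l) buildNormalPattern(
#'                 lapply(coh$eyes, function(e) e$profiles[[l]])))
#' pr <- coh$eyes[[1]]$profiles
#' computeIndexSet(pr$epithelium, pr$bowman, pr$stroma, pat)
#' @export
computeIndexSet <- function(epithelium, bowman, stroma, patterns = list()) {
  prof <- list(epithelium = epithelium, bowman = bowman, stroma = stroma)
  pre <- c(epithelium = "E", bowman = "B", stroma = "S")
  vals <- stats::setNames(rep(NA_real_, 12L), .INDEX_NAMES)
  flags <- character(0)
  for (l in names(prof)) {
    p <- prof[[l]]
    if (is.null(p)) stop("missing ", l, " profile")
    ei <- tryCatch(ectasiaIndices(p), error = function(e)
      stop(l, ": ", conditionMessage(e), call. = FALSE))
    vals[paste0(pre[l], "EI")] <- ei[["EI"]]
    vals[paste0(pre[l], "EI_MAX")] <- ei[["EI_MAX"]]
    vals[paste0(pre[l], "PV")] <- tryCatch(profileVariation(p),
      error = function(e) stop(l, ": ", conditionMessage(e), call. = FALSE))
    if (!is.null(patterns[[l]]))
      vals[paste0(pre[l], "PSD")] <- patternSD(p, patterns[[l]])
    else
      flags <- c(flags, sprintf("%sPSD unset: no %s pattern", pre[l], l))
    nExcl <- sum(!p@valid)
    if (nExcl > 0)
      flags <- c(flags, sprintf("%s: %d bin(s) excluded", l, nExcl))
  }
  subj <- epithelium@subject
  new("IndexSet", subject = if (is.na(subj)) "" else subj,
      values = vals, flags = flags)
}

#' Index table of a cohort
#'
#' One row per eye with group label and the twelve indices, suitable for
#' the group statistics stage.
#'
#' @param cohort a `kc_cohort` from [generateCohort()] (profiles type),
#'   or a list of per-eye lists with elements `profiles`, `group`,
#'   `subject`.
#' @param patterns named list of [NormalPattern-class] objects.
#' @return a data.frame with columns `subject`, `group` and the indices.
#' @export
cohortIndexTable <- function(cohort, patterns) {
  eyes <- if (inherits(cohort, "kc_cohort")) cohort$eyes else cohort
  rows <- lapply(eyes, function(e) {
    ix <- computeIndexSet(e$profiles$epithelium, e$profiles$bowman,
                          e$profiles$stroma, patterns)
    data.frame(subject = e$subject, group = e$group,
               as.list(ix@values), check.names = FALSE)
  })
  do.call(rbind, rows)
}
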