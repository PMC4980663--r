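#' @describeIn ScanGeometry-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %d x %d px, %.2f mm depth (air) x %.2f mm width, n = %.3f\n",
              object@axialPixels, object@lateralPixels,
              object@axialExtentAir, object@lateralExtent,
              object@refractiveIndex))
  cat(sprintf("  lateral pitch %.4f mm/A-scan; analysis window %d A-scans (%.2f mm)\n",
              lateralPitch(object), windowAScans(object), windowChord(object)))
})

#' @describeIn BScan-class compact display
#' @export
setMethod("show", "BScan", function(object) {
  cat(sprintf("BScan (%s): %d x %d px, intensity [%.2f, %.2f]\n",
              object@region, nrow(object@intensity), ncol(object@intensity),
              min(object@intensity), max(object@intensity)))
})

#' @describeIn BoundarySet-class compact display
#' @export
setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet (%s region):\n", object@region))
  for (i in .INTERFACES) {
    tr <- object@traces[[i]]
    cat(sprintf("  %-18s %d/%d columns valid\n", i, sum(tr@valid),
                length(tr@valid)))
  }
  if (length(object@clipped))
    cat(sprintf("  %d column(s) clipped to preserve ordering\n",
                length(object@clipped)))
})

#' @describeIn VerticalProfile-class compact display
#' @export
setMethod("show", "VerticalProfile", function(object) {
  cat(sprintf("VerticalProfile (%s%s): %d bins of %.3f mm, span %.1f mm\n",
              object@layer,
              if (!is.na(object@subject)) paste0(", ", object@subject) else "",
              length(object@values), object@binWidth,
              length(object@values) * object@binWidth))
  cat(sprintf("  thickness %.1f-%.1f um, %d bin(s) excluded\n",
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE), sum(!object@valid)))
})

#' @describeIn IndexSet-class compact display
#' @export
setMethod("show", "IndexSet", function(object) {
  cat(sprintf("IndexSet%s:\n",
              if (nzchar(object@subject)) paste0(" (", object@subject, ")") else ""))
  print(round(object@values, 2))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @describeIn DiscriminantModel-class compact display
#' @export
setMethod("show", "DiscriminantModel", function(object) {
  if (object@empty) {
    cat("DiscriminantModel: empty (no feature passed F-to-enter",
        object@fEnter, ")\n")
    return(invisible(NULL))
  }
  cat("DiscriminantModel (diseased scores higher):\n")
  for (i in seq_along(object@features))
    cat(sprintf("  step %d: %s  coef %+.4f  Wilks lambda %.4f\n", i,
                object@features[i], object@coefficients[i], object@lambda[i]))
  cat(sprintf("  intercept %+.4f; F-to-enter > %.2f\n", object@intercept,
              object@fEnter))
})

#' @describeIn ROCResult-class compact display
#' @export
setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.3f; cutoff %.3f (disease %s) -> sens %.0f%%, spec %.0f%%\n",
              object@auc, object@cutoff, object@direction,
              100 * object@sensAtCutoff, 100 * object@specAtCutoff))
})

#' @describeIn GroundTruthCornea-class compact display
#' @export
setMethod("show", "GroundTruthCornea", function(object) {
  cat(sprintf("GroundTruthCornea %s (%s): R = %.2f mm, Bowman edge +/-%.2f mm\n",
              object@subject, object@group, object@anteriorRadius,
              object@bowmanEdgeArc))
  cat(sprintf("  cone: centre %.2f mm, sigma %.2f mm, depth (%s) um\n",
              object@coneCenter, object@coneWidth,
              paste(object@coneDepth, collapse = "/")))
})
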