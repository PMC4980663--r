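#' @import methods
NULL

.INTERFACES <- c("air_epithelium", "epithelium_bowman", "bowman_stroma",
                 "stroma_posterior")
.LAYERS  <- c("epithelium", "bowman", "stroma")
.REGIONS <- c("inferior", "central", "superior")
.GROUPS  <- c("normal", "subclinical_kc", "kc")
.ZONES_PER_REGION <- 10L

#' Physical calibration of a UHR-OCT B-scan
#'
#' A `ScanGeometry` records how pixels of a B-scan map to physical
#' distances: the pixel grid, the axial scan depth measured in air, the
#' lateral scan width, and the corneal group refractive index used to
#' convert optical to geometric depth inside tissue.
#'
#' The default instance (1365 x 2048 px, 2.02 mm depth in air, 8.66 mm
#' width, index 1.389) corresponds to a custom 840-nm UHR-OCT system; with
#' it, 100 A-scans span a 0.42-mm chord and the 1,000-A-scan analysis
#' window spans 4.23 mm.
#'
#' @slot axialPixels integer, rows per B-scan.
#' @slot lateralPixels integer, A-scans (columns) per B-scan.
#' @slot axialExtentAir numeric, scan depth in air (mm).
#' @slot lateralExtent numeric, scan width (mm).
#' @slot refractiveIndex numeric, corneal refractive index.
#' @aliases ScanGeometry-class
#' @export
setClass("ScanGeometry",
  representation(axialPixels = "integer", lateralPixels = "integer",
                 axialExtentAir = "numeric", lateralExtent = "numeric",
                 refractiveIndex = "numeric"),
  prototype(axialPixels = 1365L, lateralPixels = 2048L,
            axialExtentAir = 2.02, lateralExtent = 8.66,
            refractiveIndex = 1.389))

setValidity("ScanGeometry", function(object) {
  v <- c(object@axialPixels, object@lateralPixels, object@axialExtentAir,
         object@lateralExtent, object@refractiveIndex)
  if (length(v) != 5L || any(!is.finite(v)) || any(v <= 0))
    return("all geometry fields must be single positive finite numbers")
  TRUE
})

#' @param axialPixels,lateralPixels,axialExtentAir,lateralExtent,refractiveIndex
#'   see the class slots.
#' @return a `ScanGeometry` object.
#' @examples
#' g <- scanGeometry()
#' lateralPitch(g) * 100   # chord spanned by one 100-A-scan zone (mm)
#' @rdname ScanGeometry-class
#' @export
scanGeometry <- function(axialPixels = 1365L, lateralPixels = 2048L,
                         axialExtentAir = 2.02, lateralExtent = 8.66,
                         refractiveIndex = 1.389) {
  new("ScanGeometry", axialPixels = as.integer(axialPixels),
      lateralPixels = as.integer(lateralPixels),
      axialExtentAir = axialExtentAir, lateralExtent = lateralExtent,
      refractiveIndex = refractiveIndex)
}

#' A single OCT B-scan
#'
#' Grayscale intensities in `[0, 1]`, rows axial (top = anterior), columns
#' lateral.  By package convention columns run inferior to superior.
#'
#' @slot intensity numeric matrix (axial rows x lateral columns).
#' @slot region one of `"central"`, `"superior"`, `"inferior"`.
#' @slot geometry the [ScanGeometry-class] of the scan.
#' @aliases BScan-class
#' @export
setClass("BScan",
  representation(intensity = "matrix", region = "character",
                 geometry = "ScanGeometry"))

setValidity("BScan", function(object) {
  m <- object@intensity
  if (!is.numeric(m) || nrow(m) < 3L || ncol(m) < 3L)
    return("intensity must be a numeric matrix with at least 3 rows and 3 columns")
  if (any(!is.finite(m)))
    return("intensity must be finite everywhere")
  if (!(object@region %in% .REGIONS))
    return(sprintf("region must be one of %s", paste(.REGIONS, collapse = ", ")))
  TRUE
})

#' One corneal interface trace
#'
#' Sub-pixel axial position of an interface at every column of a B-scan,
#' with a per-column validity mask.
#'
#' @slot interface interface label.
#' @slot position numeric, axial position per column (row units; NA where
#'   invalid).
#' @slot valid logical, per-column validity.
#' @aliases BoundaryTrace-class
#' @export
setClass("BoundaryTrace",
  representation(interface = "character", position = "numeric",
                 valid = "logical"))

setValidity("BoundaryTrace", function(object) {
  if (!(object@interface %in% .INTERFACES))
    return("unknown interface label")
  if (length(object@position) != length(object@valid))
    return("position and valid must have equal length")
  if (any(object@valid & !is.finite(object@position)))
    return("valid columns must have finite positions")
  TRUE
})

#' The four interface traces of one B-scan
#'
#' @slot traces named list of four [BoundaryTrace-class] objects in
#'   anterior-to-posterior order.
#' @slot region region label of the source scan.
#' @slot geometry the source [ScanGeometry-class].
#' @slot clipped integer, columns where the ordering invariant had to be
#'   enforced by clipping.
#' @aliases BoundarySet-class
#' @export
setClass("BoundarySet",
  representation(traces = "list", region = "character",
                 geometry = "ScanGeometry", clipped = "integer"))

setValidity("BoundarySet", function(object) {
  if (!identical(names(object@traces), .INTERFACES))
    return("traces must be named by the four interfaces in order")
  n <- unique(vapply(object@traces, function(t) length(t@position), 1L))
  if (length(n) != 1L)
    return("all traces must cover the same columns")
  pos <- vapply(object@traces, slot, numeric(n), "position")
  ok  <- vapply(object@traces, slot, logical(n), "valid")
  for (k in 1:3) {
    both <- ok[, k] & ok[, k + 1L]
    if (any(both) && any(pos[both, k] > pos[both, k + 1L] + 1e-6))
      return(sprintf("interface ordering violated between %s and %s",
                     .INTERFACES[k], .INTERFACES[k + 1L]))
  }
  TRUE
})

#' Refraction-corrected boundary positions
#'
#' Geometric (physically corrected) coordinates of the four interfaces,
#' one point per A-scan, in millimetres in the scan frame (x lateral,
#' z axial, z increasing posteriorly).
#'
#' @slot lateral,axial 4 x nAScan numeric matrices (mm), rows named by
#'   interface.
#' @slot valid 4 x nAScan logical matrix.
#' @slot region region label.
#' @slot geometry source [ScanGeometry-class].
#' @aliases CorrectedBoundarySet-class
#' @export
setClass("CorrectedBoundarySet",
  representation(lateral = "matrix", axial = "matrix", valid = "matrix",
                 region = "character", geometry = "ScanGeometry"))

setValidity("CorrectedBoundarySet", function(object) {
  d <- dim(object@lateral)
  if (!identical(d, dim(object@axial)) || !identical(d, dim(object@valid)))
    return("lateral, axial and valid must share dimensions")
  if (d[1L] != 4L || !identical(rownames(object@lateral), .INTERFACES))
    return("rows must be the four interfaces")
  if (any(object@valid & !is.finite(object@axial)))
    return("valid entries must be finite")
  TRUE
})

#' Per-A-scan layer thickness
#'
#' Thickness of one corneal layer measured perpendicular to the anterior
#' surface, one value per A-scan.
#'
#' @slot layer `"epithelium"`, `"bowman"` or `"stroma"`.
#' @slot thickness numeric, micrometres.
#' @slot lateral numeric, lateral position of the anterior-surface foot
#'   point (mm, scan frame).
#' @slot valid logical mask.
#' @slot region region label.
#' @slot geometry source [ScanGeometry-class].
#' @aliases AScanThicknessProfile-class
#' @export
setClass("AScanThicknessProfile",
  representation(layer = "character", thickness = "numeric",
                 lateral = "numeric", valid = "logical",
                 region = "character", geometry = "ScanGeometry"))

setValidity("AScanThicknessProfile", function(object) {
  if (!(object@layer %in% .LAYERS)) return("unknown layer")
  if (length(object@thickness) != length(object@valid) ||
      length(object@thickness) != length(object@lateral))
    return("thickness, lateral and valid must have equal length")
  if (any(object@valid & !(object@thickness > 0)))
    return("valid thicknesses must be positive")
  TRUE
})

#' Ten-zone regional thickness profile
#'
#' Block means of the analysis window of one region: the window is split
#' into 10 zones ordered inferior to superior, each nominally aggregating
#' 100 A-scans (a 0.42-mm chord with the default geometry).
#'
#' @slot region,layer labels.
#' @slot zoneMeans numeric(10), zone mean thickness (um).
#' @slot zoneN integer(10), valid A-scans per zone.
#' @slot partial logical(10), TRUE where fewer than 60 percent of the
#'   zone's A-scans were valid.
#' @slot zoneChord numeric, zone chord width (mm).
#' @slot aScansPerZone integer.
#' @aliases ZonalProfile-class
#' @export
setClass("ZonalProfile",
  representation(region = "character", layer = "character",
                 zoneMeans = "numeric", zoneN = "integer",
                 partial = "logical", zoneChord = "numeric",
                 aScansPerZone = "integer"))

setValidity("ZonalProfile", function(object) {
  if (length(object@zoneMeans) != .ZONES_PER_REGION)
    return("exactly 10 zones are required")
  if (length(object@zoneN) != .ZONES_PER_REGION ||
      length(object@partial) != .ZONES_PER_REGION)
    return("zoneN and partial must have length 10")
  if (!(object@region %in% .REGIONS)) return("unknown region")
  if (!(object@layer %in% .LAYERS)) return("unknown layer")
  TRUE
})

#' Entire vertical meridian thickness profile
#'
#' Zonal thicknesses of one layer registered onto a common chord axis
#' anchored at the corneal apex.  Bin `j` covers chord
#' `[j*w, (j+1)*w)` millimetres with `w` the zone chord (0.423 mm by
#' default); negative indices are inferior.  With the default geometry the
#' profile spans 26 bins, about 11 mm from the inferior to the superior
#' edge of Bowman's layer.
#'
#' @slot layer layer label.
#' @slot binIndex integer vector of bin indices (contiguous).
#' @slot values numeric, bin thickness (um).
#' @slot nRegions integer, regions contributing to each bin.
#' @slot valid logical, FALSE for bins excluded (partial coverage).
#' @slot binWidth numeric, bin chord width (mm).
#' @slot subject,group optional identifiers.
#' @aliases VerticalProfile-class
#' @export
setClass("VerticalProfile",
  representation(layer = "character", binIndex = "integer",
                 values = "numeric", nRegions = "integer",
                 valid = "logical", binWidth = "numeric",
                 subject = "character", group = "character"),
  prototype(subject = NA_character_, group = NA_character_))

setValidity("VerticalProfile", function(object) {
  n <- length(object@binIndex)
  if (length(object@values) != n || length(object@nRegions) != n ||
      length(object@valid) != n)
    return("binIndex, values, nRegions and valid must have equal length")
  if (n > 1L && !all(diff(object@binIndex) == 1L))
    return("bins must be contiguous")
  if (any(object@nRegions < 1L))
    return("every bin must be covered by at least one region")
  if (!(object@layer %in% .LAYERS)) return("unknown layer")
  TRUE
})

#' Normal-cohort reference pattern
#'
#' Per-bin mean thickness of a reference cohort of normal eyes, on the
#' same bin axis as [VerticalProfile-class]; used by the pattern
#' standard-deviation indices.
#'
#' @slot layer layer label.
#' @slot binIndex integer bin indices.
#' @slot mean numeric, per-bin mean thickness (um).
#' @slot n integer, eyes contributing.
#' @slot binWidth numeric (mm).
#' @aliases NormalPattern-class
#' @export
setClass("NormalPattern",
  representation(layer = "character", binIndex = "integer",
                 mean = "numeric", n = "integer", binWidth = "numeric"))

setValidity("NormalPattern", function(object) {
  if (object@n < 1L) return("n must be at least 1")
  if (length(object@mean) != length(object@binIndex))
    return("mean and binIndex must have equal length")
  TRUE
})

.INDEX_NAMES <- c("EEI", "BEI", "SEI", "EEI_MAX", "BEI_MAX", "SEI_MAX",
                  "EPV", "BPV", "SPV", "EPSD", "BPSD", "SPSD")

#' The twelve diagnostic thickness indices of one eye
#'
#' Ectasia indices (EI: minimum inferior-half thickness over mean
#' superior-half thickness, x100; EI-MAX uses the superior maximum),
#' profile variations (PV: RMS about the subject's own profile mean) and
#' pattern standard deviations (PSD: RMS about the normal reference
#' pattern), for the epithelium (E), Bowman's layer (B) and stroma (S).
#'
#' @slot subject subject identifier.
#' @slot values named numeric(12) in the order EEI, BEI, SEI, EEI_MAX,
#'   BEI_MAX, SEI_MAX, EPV, BPV, SPV, EPSD, BPSD, SPSD.
#' @slot flags character, notes about excluded bins or unset indices.
#' @aliases IndexSet-class
#' @export
setClass("IndexSet",
  representation(subject = "character", values = "numeric",
                 flags = "character"))

setValidity("IndexSet", function(object) {
  if (!identical(names(object@values), .INDEX_NAMES))
    return("values must be named by the twelve indices")
  v <- object@values
  ei <- v[c("EEI", "BEI", "SEI")]; eim <- v[c("EEI_MAX", "BEI_MAX", "SEI_MAX")]
  if (any(!is.na(ei) & !is.na(eim) & eim > ei + 1e-9))
    return("EI_MAX must not exceed EI for any layer")
  if (any(!is.na(v[7:12]) & v[7:12] < 0))
    return("PV and PSD must be non-negative")
  TRUE
})

#' Stepwise linear discriminant model
#'
#' Result of forward Wilks-lambda stepwise selection followed by a linear
#' discriminant fit.  Scores are oriented so diseased eyes score higher
#' than normal eyes, are scaled to unit pooled within-group variance and
#' centred at the grand mean.
#'
#' @slot features character, selected features in entry order.
#' @slot coefficients numeric, one per selected feature.
#' @slot intercept numeric.
#' @slot lambda numeric, Wilks' lambda after each entry step.
#' @slot fEnter numeric, F-to-enter threshold.
#' @slot groups character, group levels used in fitting.
#' @slot normalGroup character, the reference (lowest-scoring) group.
#' @slot empty logical, TRUE when no feature passed the entry threshold.
#' @aliases DiscriminantModel-class
#' @export
setClass("DiscriminantModel",
  representation(features = "character", coefficients = "numeric",
                 intercept = "numeric", lambda = "numeric",
                 fEnter = "numeric", groups = "character",
                 normalGroup = "character", empty = "logical"))

setValidity("DiscriminantModel", function(object) {
  if (object@empty) return(TRUE)
  if (length(object@features) != length(object@coefficients))
    return("one coefficient per feature is required")
  if (length(object@lambda) != length(object@features))
    return("one lambda per entry step is required")
  if (any(diff(c(1, object@lambda)) >= 0))
    return("Wilks' lambda must strictly decrease along the entry sequence")
  TRUE
})

#' Empirical ROC curve result
#'
#' @slot thresholds numeric, sorted candidate cutoffs.
#' @slot sensitivity,specificity numeric, per threshold.
#' @slot auc numeric, trapezoidal area under the curve.
#' @slot cutoff numeric, Youden-optimal cutoff on the original score scale.
#' @slot sensAtCutoff,specAtCutoff numeric.
#' @slot direction `"higher"` or `"lower"`: the direction in which scores
#'   indicate disease.
#' @aliases ROCResult-class
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric",
                 cutoff = "numeric", sensAtCutoff = "numeric",
                 specAtCutoff = "numeric", direction = "character"))

setValidity("ROCResult", function(object) {
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    return("AUC must lie in [0, 1]")
  if (any(object@sensitivity < -1e-12 | object@sensitivity > 1 + 1e-12) ||
      any(object@specificity < -1e-12 | object@specificity > 1 + 1e-12))
    return("sensitivity and specificity must lie in [0, 1]")
  TRUE
})

#' Ground-truth synthetic cornea
#'
#' Continuous per-layer thickness of a simulated cornea as a function of
#' meridian (arc) position, together with the anterior-surface geometry.
#' Thickness is baseline profile plus a subject-level offset minus a
#' Gaussian cone-shaped localized thinning.
#'
#' @slot subject,group identifiers.
#' @slot anteriorRadius numeric, anterior curvature radius (mm).
#' @slot bowmanEdgeArc numeric, arc distance from apex to either Bowman's
#'   layer edge (mm).
#' @slot baseline list of three functions (one per layer) mapping meridian
#'   position (mm) to baseline thickness (um).
#' @slot subjectOffset numeric(3), per-layer additive offset (um).
#' @slot coneCenter,coneWidth numeric, Gaussian cone position and sigma (mm).
#' @slot coneDepth numeric(3), per-layer maximal thinning (um).
#' @slot seed integer used to draw the eye.
#' @aliases GroundTruthCornea-class
#' @export
setClass("GroundTruthCornea",
  representation(subject = "character", group = "character",
                 anteriorRadius = "numeric", bowmanEdgeArc = "numeric",
                 baseline = "list", subjectOffset = "numeric",
                 coneCenter = "numeric", coneWidth = "numeric",
                 coneDepth = "numeric", seed = "integer"))

setValidity("GroundTruthCornea", function(object) {
  if (!(object@group %in% .GROUPS)) return("unknown group")
  if (length(object@baseline) != 3L || !all(vapply(object@baseline, is.function, TRUE)))
    return("baseline must hold one function per layer")
  if (any(object@coneDepth < 0)) return("coneDepth must be non-negative")
  if (object@anteriorRadius <= 0 || object@bowmanEdgeArc <= 0)
    return("anteriorRadius and bowmanEdgeArc must be positive")
  TRUE
})

#' Synthetic cohort parameters for one group
#'
#' Defines the thickness distribution of one diagnostic group: regional
#' anchor means and standard deviations per layer (superior / central /
#' inferior window means), subject-level offset SDs, per-zone measurement
#' noise, the Gaussian cone, anterior curvature and rendering noise.
#' Defaults for the three groups encode the regional thickness structure
#' of normal, sub-clinical keratoconic and keratoconic corneas.
#'
#' @slot group group label.
#' @slot anchorMeans 3x3 numeric matrix (layers x regions), target
#'   regional window mean thickness (um).
#' @slot anchorSDs 3x3 numeric matrix, regional between-eye SDs (um).
#' @slot betweenEyeSD numeric(3), per-layer subject offset SD (um).
#' @slot zoneNoiseSD numeric(3), per-layer per-zone measurement noise SD (um).
#' @slot coneCenter numeric, cone chord position (mm, negative inferior);
#'   NA draws uniformly from `coneCenterRange` per eye.
#' @slot coneCenterRange numeric(2).
#' @slot coneWidth numeric, Gaussian sigma (mm).
#' @slot coneDepth numeric(3), per-layer maximal localized thinning (um).
#' @slot anteriorRadius numeric (mm).
#' @slot bowmanEdgeArc numeric (mm).
#' @slot noiseSD numeric, rendering intensity noise SD (on the [0,1]
#'   intensity scale).
#' @aliases SyntheticCorneaParams-class
#' @export
setClass("SyntheticCorneaParams",
  representation(group = "character", anchorMeans = "matrix",
                 anchorSDs = "matrix", betweenEyeSD = "numeric",
                 zoneNoiseSD = "numeric", coneCenter = "numeric",
                 coneCenterRange = "numeric", coneWidth = "numeric",
                 coneDepth = "numeric", anteriorRadius = "numeric",
                 bowmanEdgeArc = "numeric", noiseSD = "numeric"))

setValidity("SyntheticCorneaParams", function(object) {
  if (!(object@group %in% .GROUPS)) return("unknown group")
  if (!identical(dim(object@anchorMeans), c(3L, 3L)) ||
      !identical(dim(object@anchorSDs), c(3L, 3L)))
    return("anchorMeans and anchorSDs must be 3 x 3 (layers x regions)")
  if (any(object@anchorMeans <= 0)) return("all thickness means must be positive")
  if (any(object@coneDepth < 0)) return("coneDepth must be non-negative")
  if (object@group == "normal" && any(object@coneDepth != 0))
    return("the normal group must have coneDepth 0")
  if (object@noiseSD < 0) return("noiseSD must be non-negative")
  TRUE
})
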