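#' Full image-based analysis of one eye
#'
#' Runs the measurement chain on the three regional B-scans of one eye:
#' segmentation of the four interfaces, Snell refraction correction,
#' perpendicular thickness of the three layers, Bowman's-layer edge
#' detection, zonal averaging and registration into entire vertical
#' profiles.
#'
#' @param scans named list with elements `inferior`, `central`,
#'   `superior`, each a [BScan-class].
#' @param config a [pipelineConfig()] list.
#' @param seeds optional named list of Bowman-stroma seed points per
#'   region (passed to [segmentCornea()]).
#' @return a list with `profiles` (named list of three
#'   [VerticalProfile-class]s), `boundaries`, `corrected`, `edges` and
#'   `apexCol`.
#' @examples
#' \donttest{
#' gt <- sampleCorneaGeometry(corneaParams("normal"), seed = 3)
#' g <- scanGeometry(342L, 512L)
#' scans <- lapply(setNames(nm = c("inferior", "central", "superior")),
#'                 function(r) renderBScan(gt, r, g, seed = 3, noiseSD = 0))
#' pr <- analyzeEye(scans)$profiles
#' }
#' @export
analyzeEye <- function(scans, config = pipelineConfig(), seeds = NULL) {
  if (!all(.REGIONS %in% names(scans)))
    stop("scans must contain the regions ", paste(.REGIONS, collapse = ", "))
  segCfg <- configSegmentation(config)
  gapTol <- config$profile$gap_tolerance
  boundaries <- corrected <- edges <- list()
  for (r in .REGIONS) {
    boundaries[[r]] <- segmentCornea(scans[[r]], segCfg, seeds = seeds[[r]])
    corrected[[r]] <- refractionCorrect(boundaries[[r]])
    edges[[r]] <- if (r == "central")
      tryCatch(detectBowmanEdges(boundaries[[r]], gapTol),
               error = function(e) integer(0))
    else detectBowmanEdges(boundaries[[r]], gapTol)
  }
  apexCol <- apexColumn(corrected$central)
  profiles <- lapply(stats::setNames(nm = .LAYERS), function(l) {
    zps <- lapply(stats::setNames(nm = .REGIONS), function(r) {
      thick <- perpendicularThickness(corrected[[r]], l)
      zonalAverage(thick, edges = edges[[r]],
                   apexCol = if (r == "central") apexCol else NULL)
    })
    registerVerticalProfile(zps$inferior, zps$central, zps$superior,
                            semiSpanBins = config$profile$semi_span_bins)
  })
  list(profiles = profiles, boundaries = boundaries, corrected = corrected,
       edges = edges, apexCol = apexCol)
}

#' Simulate and analyse a complete study
#'
#' End-to-end reproduction of the study design on synthetic cohorts: a
#' normal reference cohort establishes the per-layer pattern averages
#' (Normal Group I), a held-out normal cohort (Normal Group II) enters
#' the comparisons, and the twelve indices of every eye feed the ANOVA,
#' the forward stepwise discriminant analysis and the ROC analyses of
#' each patient group against the held-out normals.
#'
#' @param nNormalRef,nNormal,nSubclinical,nKC eyes per cohort.
#' @param seed master seed.
#' @param fEnter F-to-enter threshold of the stepwise selection.
#' @param paramsList optional named list of per-group
#'   [SyntheticCorneaParams-class] overrides.
#' @return a list with `patterns`, `indexTable` (eyes x indices with
#'   group labels), `report` (the per-index performance table from
#'   [diagnosticReport()]), `model` (the [DiscriminantModel-class]),
#'   `scores` (per-eye discriminant scores), `scoreSummary` (group means
#'   and SDs of the score) and `scoreROC` (ROC of the score for each
#'   patient group versus normal).
#' @export
runStudy <- function(nNormalRef = 20L, nNormal = 20L, nSubclinical = 20L,
                     nKC = 20L, seed = 1L, fEnter = 3.84,
                     paramsList = NULL) {
  seeds <- .subSeeds(seed, 2L)
  refParams <- if (!is.null(paramsList) && "normal" %in% names(paramsList))
    paramsList["normal"] else NULL
  refCoh <- generateCohort(c(normal = nNormalRef), seeds[1L],
                           paramsList = refParams)
  mainCoh <- generateCohort(c(normal = nNormal,
                              subclinical_kc = nSubclinical, kc = nKC),
                            seeds[2L], paramsList = paramsList)
  patterns <- lapply(stats::setNames(nm = .LAYERS), function(l)
    buildNormalPattern(lapply(refCoh$eyes, function(e) e$profiles[[l]])))
  indexTable <- cohortIndexTable(mainCoh, patterns)
  report <- diagnosticReport(indexTable)
  model <- stepwiseLda(indexTable[, .INDEX_NAMES], indexTable$group,
                       fEnter = fEnter, normalGroup = "normal")
  scores <- if (!model@empty) discriminantScore(model, indexTable) else NULL
  scoreSummary <- scoreROC <- NULL
  if (!is.null(scores)) {
    scoreSummary <- do.call(rbind, lapply(split(scores, indexTable$group),
      function(s) data.frame(mean = mean(s), sd = stats::sd(s))))
    scoreROC <- lapply(stats::setNames(nm = c("subclinical_kc", "kc")),
      function(grp) {
        keep <- indexTable$group %in% c("normal", grp)
        rocAnalysis(scores[keep], indexTable$group[keep] == grp, "higher")
      })
  }
  list(patterns = patterns, indexTable = indexTable, report = report,
       model = model, scores = scores, scoreSummary = scoreSummary,
       scoreROC = scoreROC, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
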