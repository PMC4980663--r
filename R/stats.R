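#' Per-variable one-way ANOVA across diagnostic groups
#'
#' Fixed-effects one-way ANOVA (via [stats::aov()]) of each variable
#' against the group factor, with per-group descriptives: mean, SD and
#' 95 percent confidence interval of the mean.  Optionally Dunnett-style
#' post-hoc contrasts of each patient group against the reference group.
#'
#' @param values numeric matrix or data.frame, one row per eye, one
#'   column per variable.
#' @param labels group labels (factor or character), one per eye.
#' @param dunnett logical, add Dunnett contrasts versus `reference`
#'   (needs the multcomp package).
#' @param reference reference group for the Dunnett contrasts.
#' @return a data.frame with one row per variable: `F`, `p`, then per
#'   group `<group>_mean`, `<group>_sd`, `<group>_lo`, `<group>_hi`; when
#'   `dunnett` is TRUE also `<group>_p_vs_ref` columns.
#' @export
anovaGroups <- function(values, labels, dunnett = FALSE, reference = NULL) {
  values <- as.data.frame(values)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (any(table(g) < 2L)) stop("every group needs at least 2 observations")
  if (!is.null(reference)) g <- stats::relevel(g, reference)
  out <- lapply(names(values), function(v) {
    y <- values[[v]]
    fit <- stats::aov(y ~ g)
    an <- stats::anova(fit)
    row <- data.frame(variable = v, F = an$`F value`[1L], p = an$`Pr(>F)`[1L])
    for (lev in levels(g)) {
      yi <- y[g == lev]
      ci <- stats::qt(0.975, length(yi) - 1L) * stats::sd(yi) / sqrt(length(yi))
      row[[paste0(lev, "_mean")]] <- mean(yi)
      row[[paste0(lev, "_sd")]] <- stats::sd(yi)
      row[[paste0(lev, "_lo")]] <- mean(yi) - ci
      row[[paste0(lev, "_hi")]] <- mean(yi) + ci
    }
    if (dunnett) {
      if (!requireNamespace("multcomp", quietly = TRUE))
        stop("Dunnett contrasts need the multcomp package")
      dfit <- stats::aov(y ~ g)
      dn <- summary(multcomp::glht(dfit, linfct = multcomp::mcp(g = "Dunnett")))
      pv <- as.numeric(dn$test$pvalues)
      for (i in seq_along(pv))
        row[[paste0(levels(g)[i + 1L], "_p_vs_ref")]] <- pv[i]
    }
    row
  })
  do.call(rbind, out)
}

#' Wilks' lambda of a feature set
#'
#' Ratio of the determinant of the within-group scatter to the total
#' scatter of the selected columns; 1 for no separation, smaller values
#' for better group separation.
#'
#' @param x numeric matrix, eyes x features.
#' @param groups group factor.
#' @return numeric in (0, 1].
#' @export
wilksLambda <- function(x, groups) {
  x <- as.matrix(x)
  g <- factor(groups)
  tot <- crossprod(scale(x, scale = FALSE))
  win <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    win <- win + crossprod(scale(xi, scale = FALSE))
  }
  det(win) / det(tot)
}

## Scatter matrices of the full feature set (computed once per fit)
.scatter <- function(x, g) {
  tot <- crossprod(scale(x, scale = FALSE))
  win <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g))
    win <- win + crossprod(scale(x[g == lev, , drop = FALSE], scale = FALSE))
  list(within = win, total = tot)
}

#' Forward stepwise linear discriminant analysis
#'
#' Forward Wilks-lambda selection: at each step the candidate that
#' minimises the Wilks' lambda of the enlarged set enters, provided its
#' partial F-to-enter exceeds `fEnter` (3.84 by default, the 0.05
#' critical value of F with one numerator degree of freedom at large n);
#' selection stops otherwise.  Ties in lambda break lexicographically by
#' feature name, so the result does not depend on column order.  The
#' linear discriminant function is then fitted on the selected set and
#' oriented so diseased (non-reference) eyes score higher than the
#' reference group; scores are scaled to unit pooled within-group
#' variance and centred at the grand mean.
#'
#' With two groups the coefficient vector is Fisher's
#' `solve(pooled covariance) %*% (mean difference)`; with more groups it
#' is the leading canonical variate of the within/between eigenproblem.
#'
#' @param x numeric matrix or data.frame of candidate features.
#' @param groups group labels, one per row of `x`.
#' @param fEnter F-to-enter threshold.
#' @param normalGroup the reference (expected lowest-scoring) group;
#'   defaults to `"normal"` if present, else the first level.
#' @return a [DiscriminantModel-class]; when no feature passes at step 1
#'   the model is returned with `empty = TRUE`.
#' @export
stepwiseLda <- function(x, groups, fEnter = 3.84, normalGroup = NULL) {
  x <- as.matrix(as.data.frame(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  g <- factor(groups)
  nG <- nlevels(g)
  n <- nrow(x)
  if (nG < 2L) stop("at least two groups are required")
  if (is.null(normalGroup))
    normalGroup <- if ("normal" %in% levels(g)) "normal" else levels(g)[1L]

  selected <- character(0)
  lambdaTrail <- numeric(0)
  lambdaCur <- 1
  repeat {
    cand <- setdiff(colnames(x), selected)
    if (length(cand) == 0L) break
    lam <- vapply(sort(cand), function(j)
      wilksLambda(x[, c(selected, j), drop = FALSE], g), 0)
    best <- names(lam)[which.min(lam)]       # sorted names: lexicographic ties
    lamBest <- lam[[best]]
    p <- length(selected)
    Fenter <- (lambdaCur / lamBest - 1) * (n - nG - p) / (nG - 1)
    if (!is.finite(Fenter) || Fenter <= fEnter || lamBest >= lambdaCur) break
    selected <- c(selected, best)
    lambdaTrail <- c(lambdaTrail, lamBest)
    lambdaCur <- lamBest
  }
  if (length(selected) == 0L)
    return(new("DiscriminantModel", features = character(0),
               coefficients = numeric(0), intercept = 0,
               lambda = numeric(0), fEnter = fEnter,
               groups = levels(g), normalGroup = normalGroup, empty = TRUE))

  xs <- x[, selected, drop = FALSE]
  sc <- .scatter(xs, g)
  Sp <- sc$within / (n - nG)                 # pooled covariance
  if (rcond(Sp) < 1e-12) stop("singular pooled covariance among selected features")
  if (nG == 2L) {
    mdiff <- colMeans(xs[g == levels(g)[2L], , drop = FALSE]) -
      colMeans(xs[g == levels(g)[1L], , drop = FALSE])
    w <- solve(Sp, mdiff)
  } else {
    B <- (sc$total - sc$within) / (nG - 1)
    ev <- eigen(solve(sc$within / (n - nG), B))
    w <- Re(ev$vectors[, which.max(Re(ev$values))])
  }
  w <- w / sqrt(drop(t(w) %*% Sp %*% w))     # unit within-group variance
  raw <- drop(xs %*% w)
  if (mean(raw[g != normalGroup]) < mean(raw[g == normalGroup])) { w <- -w; raw <- -raw }
  new("DiscriminantModel", features = selected,
      coefficients = stats::setNames(as.numeric(w), selected),
      intercept = -mean(raw), lambda = lambdaTrail, fEnter = fEnter,
      groups = levels(g), normalGroup = normalGroup, empty = FALSE)
}

#' Score eyes with a discriminant model
#'
#' `score = intercept + sum(coefficient * feature)`; diseased eyes score
#' higher by the model's orientation.
#'
#' @param model a [DiscriminantModel-class].
#' @param data data.frame or matrix with the model's feature columns.
#' @return numeric score per row.
#' @export
discriminantScore <- function(model, data) {
  if (model@empty) stop("empty discriminant model: no feature passed entry")
  data <- as.data.frame(data)
  miss <- setdiff(model@features, names(data))
  if (length(miss)) stop("missing feature value(s): ", paste(miss, collapse = ", "))
  xm <- as.matrix(data[, model@features, drop = FALSE])
  drop(xm %*% model@coefficients) + model@intercept
}

#' Empirical ROC analysis
#'
#' ROC over all distinct score thresholds, with AUC by the trapezoidal
#' rule (identical to the concordance probability with ties counted one
#' half), and the Youden-optimal cutoff (maximising sensitivity +
#' specificity - 1; ties broken toward higher sensitivity).
#'
#' @param scores numeric score per eye.
#' @param labels positive-class indicator: logical, or a factor/character
#'   with `positive` naming the diseased class.
#' @param direction `"higher"` when larger scores indicate disease,
#'   `"lower"` for indices where disease lowers the value.
#' @param positive the diseased label when `labels` is not logical.
#' @return an [ROCResult-class].
#' @examples
#' r <- rocAnalysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r@auc
#' @export
rocAnalysis <- function(scores, labels, direction = c("higher", "lower"),
                        positive = NULL) {
  direction <- match.arg(direction)
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("non-logical labels need `positive`")
    labels <- labels == positive
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  s <- if (direction == "lower") -scores else scores
  thr <- sort(unique(s))
  cuts <- c(-Inf, thr, Inf)                 # classify positive when s >= cut
  sens <- vapply(cuts, function(ct) mean(s[labels] >= ct), 0)
  spec <- vapply(cuts, function(ct) mean(s[!labels] < ct), 0)
  ## trapezoidal AUC over (1 - spec, sens), curve ordered by decreasing cut
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (utils::head(sens[o], -1) + utils::tail(sens[o], -1)) / 2)
  J <- sens + spec - 1
  bestJ <- max(J)
  cand <- which(J >= bestJ - 1e-12)
  best <- cand[which.max(sens[cand])]
  cutoff <- cuts[best]
  if (direction == "lower") cutoff <- -cutoff
  new("ROCResult",
      thresholds = if (direction == "lower") rev(-cuts) else cuts,
      sensitivity = if (direction == "lower") rev(sens) else sens,
      specificity = if (direction == "lower") rev(spec) else spec,
      auc = auc, cutoff = cutoff,
      sensAtCutoff = sens[best], specAtCutoff = spec[best],
      direction = direction)
}

## direction in which each index moves with disease
.INDEX_DIRECTION <- c(EEI = "lower", BEI = "lower", SEI = "lower",
                      EEI_MAX = "lower", BEI_MAX = "lower", SEI_MAX = "lower",
                      EPV = "higher", BPV = "higher", SPV = "higher",
                      EPSD = "higher", BPSD = "higher", SPSD = "higher")

#' Diagnostic performance report
#'
#' The summary table of the full analysis: for every index, the group
#' means and SDs, the ANOVA P value across the three groups, and for each
#' patient group versus the normal reference the AUC, Youden cutoff,
#' sensitivity and specificity.  Ectasia indices count as positive below
#' the cutoff, variation/deviation indices above it.
#'
#' @param indexTable data.frame from [cohortIndexTable()]: `group` plus
#'   the twelve index columns.
#' @param normalGroup label of the reference group in `indexTable`.
#' @param patientGroups labels of the patient groups to report.
#' @return a data.frame with one row per index.
#' @export
diagnosticReport <- function(indexTable, normalGroup = "normal",
                             patientGroups = c("subclinical_kc", "kc")) {
  idx <- intersect(.INDEX_NAMES, names(indexTable))
  if (length(idx) == 0L) stop("indexTable holds no index columns")
  g <- indexTable$group
  an <- anovaGroups(indexTable[, idx, drop = FALSE], g)
  out <- data.frame(index = idx,
                    P = an$p[match(idx, an$variable)])
  for (lev in c(normalGroup, patientGroups)) {
    xi <- indexTable[g == lev, idx, drop = FALSE]
    out[[paste0(lev, "_mean")]] <- colMeans(xi)
    out[[paste0(lev, "_sd")]] <- apply(xi, 2L, stats::sd)
  }
  for (lev in patientGroups) {
    keep <- g %in% c(normalGroup, lev)
    cols <- lapply(idx, function(v) {
      r <- rocAnalysis(indexTable[[v]][keep], g[keep] == lev,
                       direction = .INDEX_DIRECTION[[v]])
      c(auc = r@auc, cutoff = r@cutoff,
        sens = 100 * r@sensAtCutoff, spec = 100 * r@specAtCutoff)
    })
    m <- do.call(rbind, cols)
    out[[paste0(lev, "_AUC")]] <- m[, "auc"]
    out[[paste0(lev, "_cutoff")]] <- m[, "cutoff"]
    out[[paste0(lev, "_sens")]] <- m[, "sens"]
    out[[paste0(lev, "_spec")]] <- m[, "spec"]
  }
  rownames(out) <- NULL
  out
}
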