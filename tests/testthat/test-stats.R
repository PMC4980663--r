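test_that("ANOVA F matches hand-computed sums of squares on a fixture", {
  y <- c(1, 2, 3, 6, 7, 8, 11, 12, 16)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anovaGroups(data.frame(y = y), g)
  gm <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, Fhand, tolerance = 1e-12)
  expect_equal(res$p, pf(Fhand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$a_mean, 2)
  expect_equal(res$c_sd, sd(c(11, 12, 16)))
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(5)
  y <- c(rnorm(8), rnorm(9, 1))
  g <- rep(c("a", "b"), c(8, 9))
  res <- anovaGroups(data.frame(y = y), g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_error(anovaGroups(data.frame(y = 1:3), c("a", "a", "b")),
               "at least 2 observations")
})

test_that("Dunnett contrasts against the reference group are reported", {
  skip_if_not_installed("multcomp")
  set.seed(9)
  y <- c(rnorm(15), rnorm(15, 3), rnorm(15))
  g <- rep(c("normal", "kc", "subclinical_kc"), each = 15)
  res <- anovaGroups(data.frame(y = y), g, dunnett = TRUE,
                     reference = "normal")
  expect_lt(res$kc_p_vs_ref, 0.01)
  expect_gt(res$subclinical_kc_p_vs_ref, 0.05)
})

test_that("type-I error of the ANOVA is near nominal under the null", {
  set.seed(17)
  p <- replicate(400, {
    y <- rnorm(60)
    anovaGroups(data.frame(y = y), rep(c("a", "b", "c"), 20))$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("Wilks' lambda is 1 without separation and small with it", {
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2)
  g <- rep(c("a", "b"), 50)
  expect_lt(abs(wilksLambda(x, g) - 1), 0.2)
  x2 <- x; x2[g == "b", 1] <- x2[g == "b", 1] + 10
  expect_lt(wilksLambda(x2, g), 0.1)
})

test_that("stepwise selection finds the separating feature and rejects noise", {
  set.seed(11)
  n <- 60
  g <- rep(c("normal", "kc"), each = n / 2)
  x <- data.frame(signal = rnorm(n) + 4 * (g == "kc"),
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  m <- stepwiseLda(x, g, fEnter = 3.84)
  expect_equal(m@features[1], "signal")
  expect_false("noise1" %in% m@features && "noise2" %in% m@features &&
                 "noise3" %in% m@features)
  expect_true(all(diff(c(1, m@lambda)) < 0))
  ## identically distributed features: empty selection
  set.seed(12)
  x0 <- data.frame(a = rnorm(n), b = rnorm(n))
  m0 <- stepwiseLda(x0, g, fEnter = 3.84)
  expect_true(m0@empty)
  expect_error(discriminantScore(m0, x0), "empty")
})

test_that("two-group coefficients follow Fisher's closed form", {
  set.seed(21)
  n <- 40
  g <- rep(c("normal", "kc"), each = n / 2)
  x <- cbind(f1 = rnorm(n) + 2 * (g == "kc"), f2 = rnorm(n) + 1 * (g == "kc"))
  m <- stepwiseLda(x, g, fEnter = 0.01)
  xs <- x[, m@features, drop = FALSE]
  S <- ((n / 2 - 1) * cov(xs[g == "normal", ]) +
        (n / 2 - 1) * cov(xs[g == "kc", ])) / (n - 2)
  w <- solve(S, colMeans(xs[g == "kc", ]) - colMeans(xs[g == "normal", ]))
  ## proportional up to the variance normalisation, oriented kc-high
  ratio <- unname(m@coefficients / w)
  expect_equal(ratio[1], ratio[2], tolerance = 1e-8)
  expect_gt(ratio[1], 0)
  sc <- discriminantScore(m, as.data.frame(x))
  expect_gt(mean(sc[g == "kc"]), mean(sc[g == "normal"]))
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  ## within-group unit variance
  pooled <- (var(sc[g == "kc"]) * (n / 2 - 1) +
             var(sc[g == "normal"]) * (n / 2 - 1)) / (n - 2)
  expect_equal(pooled, 1, tolerance = 1e-8)
})

test_that("selection agrees with MASS::lda direction on the selected set", {
  set.seed(33)
  n <- 80
  g <- rep(c("normal", "kc"), each = n / 2)
  x <- data.frame(a = rnorm(n) + 1.5 * (g == "kc"),
                  b = rnorm(n) - 1.0 * (g == "kc"))
  m <- stepwiseLda(x, g, fEnter = 0.01)
  ld <- MASS::lda(x[, m@features, drop = FALSE], grouping = g)
  sc1 <- discriminantScore(m, x)
  sc2 <- as.numeric(as.matrix(x[, m@features]) %*% ld$scaling[, 1])
  expect_gt(abs(cor(sc1, sc2)), 1 - 1e-9)
})

test_that("selection is invariant to feature column order", {
  set.seed(44)
  n <- 60
  g <- rep(c("normal", "subclinical_kc", "kc"), each = n / 3)
  x <- data.frame(a = rnorm(n) + 2 * (g == "kc"),
                  b = rnorm(n) + 2 * (g != "normal"),
                  c = rnorm(n))
  m1 <- stepwiseLda(x, g)
  m2 <- stepwiseLda(x[, c("c", "b", "a")], g)
  expect_identical(m1@features, m2@features)
  expect_equal(m1@coefficients, m2@coefficients[names(m1@coefficients)])
})

test_that("score formula is the exact linear form", {
  m <- new("DiscriminantModel", features = c("x1", "x2"),
           coefficients = c(x1 = 2, x2 = -3), intercept = 0.5,
           lambda = c(0.5, 0.25), fEnter = 3.84,
           groups = c("a", "b"), normalGroup = "a", empty = FALSE)
  d <- data.frame(x1 = c(1, 2), x2 = c(0, 1))
  expect_equal(discriminantScore(m, d), c(2.5, 1.5))
  expect_error(discriminantScore(m, data.frame(x1 = 1)), "x2")
})

test_that("AUC equals concordance pair counting, with ties half-weighted", {
  set.seed(6)
  for (i in 1:25) {
    sc <- sample(seq(0, 5, by = 0.5), 14, replace = TRUE)  # forces ties
    lab <- runif(14) < 0.5
    if (!any(lab) || all(lab)) next
    r <- rocAnalysis(sc, lab)
    expect_equal(r@auc, concordanceAUC(sc, lab), tolerance = 1e-12)
  }
  ## ten hand-listed scores
  sc <- c(0.1, 0.3, 0.3, 0.4, 0.5, 0.6, 0.6, 0.8, 0.9, 0.95)
  lab <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(rocAnalysis(sc, lab)@auc, concordanceAUC(sc, lab))
})

test_that("ROC endpoints, perfect separation and degenerate input behave", {
  r <- rocAnalysis(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r@auc, 1)
  expect_equal(r@sensAtCutoff, 1)
  expect_equal(r@specAtCutoff, 1)
  o <- order(1 - r@specificity, r@sensitivity)
  expect_true(all(diff(r@sensitivity[o]) >= -1e-12))
  expect_error(rocAnalysis(1:5, rep(TRUE, 5)), "both classes")
  ## lower-direction indices: cutoff returned on the original scale
  r2 <- rocAnalysis(c(10, 9, 8, 1, 2, 3), rep(c(FALSE, TRUE), each = 3),
                    direction = "lower")
  expect_equal(r2@auc, 1)
  expect_true(r2@cutoff < 8 & r2@cutoff >= 3)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(8)
  sc <- rnorm(40); lab <- runif(40) < 0.4
  if (!any(lab)) lab[1] <- TRUE
  r1 <- rocAnalysis(sc, lab)
  r2 <- rocAnalysis(exp(sc), lab)
  expect_equal(r1@auc, r2@auc, tolerance = 1e-12)
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- round(rnorm(60), 1)
  lab <- runif(60) < 0.5
  if (!any(lab)) lab[1] <- TRUE
  if (all(lab)) lab[2] <- FALSE
  r <- rocAnalysis(sc, lab)
  ref <- pROC::roc(response = lab, predictor = sc, direction = "<",
                   quiet = TRUE)
  expect_equal(r@auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  yj <- pROC::coords(ref, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"), transpose = FALSE)
  expect_equal(r@sensAtCutoff + r@specAtCutoff,
               max(yj$sensitivity + yj$specificity), tolerance = 1e-9)
})

test_that("null scores give an AUC near one half", {
  set.seed(14)
  auc <- replicate(60, rocAnalysis(rnorm(50), rep(c(TRUE, FALSE), 25))@auc)
  expect_lt(abs(mean(auc) - 0.5), 0.05)
})
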