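test_that("points exactly on a line are fitted exactly", {
  ds <- makeLineDataset(c(10, 20, 30, 40, 50), slope = 2, intercept = 5)
  fit <- suppressWarnings(fitGlobalRegression(ds))  # perfect-fit summary
  expect_equal(slope(fit), 2)
  expect_equal(intercept(fit), 5)
  expect_equal(pearsonR(fit), 1)
})

test_that("global and cluster fits match the normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    x <- runif(n, 5, 120)
    y <- pmax(1, 80 + 0.7 * x + rnorm(n, 0, 25))
    ds <- ProteinDataset(makeCanonicalDf(x, y))
    fit <- fitGlobalRegression(ds)
    oracle <- olsOracle(x, y)
    expect_equal(slope(fit), unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(intercept(fit), unname(oracle["intercept"]),
                 tolerance = 1e-10)
    asg <- assignClusters(ds, fit)
    for (cl in names(which(clusterSizes(asg) >= 3))) {
      ids <- names(clusterLabels(asg))[clusterLabels(asg) == cl]
      sub <- records(ds)[records(ds)$protein_id %in% ids, ]
      oc <- olsOracle(sub$cell_halflife_h, sub$tissue_halflife_h)
      cf <- fitClusterRegression(ds, asg, cl)
      expect_equal(slope(cf), unname(oc["slope"]), tolerance = 1e-10)
      expect_equal(intercept(cf), unname(oc["intercept"]), tolerance = 1e-10)
    }
  }
})

test_that("fewer than 3 usable points is an insufficient-data error", {
  ds <- ProteinDataset(makeCanonicalDf(c(10, 20), c(50, 60)))
  expect_error(fitGlobalRegression(ds), "at least 3")
})

test_that("relative deviation follows its definition, including boundaries", {
  fit <- RegressionFit(slope = 1, intercept = 0)
  # Y = 55 on a line predicting 50: d = 0.10 by hand arithmetic
  ds <- ProteinDataset(makeCanonicalDf(50, 55))
  expect_equal(unname(relativeDeviation(ds, fit)), 0.1)
  # on the line: d = 0
  expect_equal(unname(relativeDeviation(
    ProteinDataset(makeCanonicalDf(50, 50)), fit)), 0)
  # boundary d = 0.10 is assigned to C2 (inclusive band)
  asg <- suppressWarnings(
    assignClusters(ProteinDataset(makeCanonicalDf(c(50, 60, 70),
                                                  c(55, 66, 77))), fit))
  expect_true(all(clusterLabels(asg) == "C2"))
  # degenerate line: fitted value <= 0
  expect_error(relativeDeviation(ProteinDataset(makeCanonicalDf(10, 50)),
                                 RegressionFit(1, -100)), "non-positive")
})

test_that("hand-built deviations get the hand-derived labels", {
  fit <- RegressionFit(slope = 1, intercept = 0)
  x <- rep(100, 6)
  d <- c(0.2, 0.15, 0.05, 0, -0.05, -0.3)
  ds <- ProteinDataset(makeCanonicalDf(x, x * (1 + d)))
  asg <- assignClusters(ds, fit)
  expect_equal(as.character(clusterLabels(asg)),
               c("C1", "C1", "C2", "C2", "C2", "C3"))
  expect_equal(unname(deviations(asg)), d)
})

test_that("all points on the line yield a pure C2 partition with warnings", {
  ds <- makeLineDataset(seq(10, 100, 10), slope = 0.6, intercept = 141)
  fit <- RegressionFit(0.6, 141)
  expect_warning(asg <- assignClusters(ds, fit), "empty cluster")
  expect_equal(unname(as.vector(clusterSizes(asg))), c(0L, 10L, 0L))
})

test_that("clusters partition the common set and shrinkage never grows C2", {
  ds <- generateDataset(liverlikePreset(seed = 14))
  fit <- fitGlobalRegression(ds)
  asg <- assignClusters(ds, fit)
  expect_equal(sum(clusterSizes(asg)), sum(isCommon(ds)))
  expect_setequal(names(clusterLabels(asg)),
                  proteinIds(ds)[isCommon(ds)])
  c2 <- clusterSizes(asg)[["C2"]]
  for (bw in c(0.08, 0.05, 0.02)) {
    smaller <- clusterSizes(assignClusters(ds, fit, bandWidth = bw))[["C2"]]
    expect_lte(smaller, c2)
    c2 <- smaller
  }
})

test_that("the within-band correlation dominates the full-set correlation", {
  ds <- generateDataset(liverlikePreset(seed = 15))
  fit <- fitGlobalRegression(ds)
  asg <- assignClusters(ds, fit)
  expect_gte(asg@withinBandR, pearsonR(fit))
})

test_that("correlation profile matches the textbook formula and signs", {
  cfg <- generatorConfig(nProteins = 1200, seed = 16,
                         propertyCorrelations = c(abundance = 0.8,
                                                  mrna = -0.5))
  ds <- generateDataset(cfg)
  asg <- assignClusters(ds, fitGlobalRegression(ds))
  prof <- correlationProfile(ds, asg)
  feats <- transformFeatures(ds)
  y <- setNames(records(ds)$tissue_halflife_h, proteinIds(ds))
  labs <- clusterLabels(asg)
  for (cl in c("C1", "C2", "C3")) {
    ids <- names(labs)[labs == cl]
    for (f in halflifeFeatures())
      expect_equal(prof@correlations[cl, f],
                   pearsonOracle(feats[ids, f], y[ids]), tolerance = 1e-12)
    # strong positive generator correlation lands in PCH, negative is out
    expect_true(pchMask(prof)[cl, "abundance"])
    expect_false(pchMask(prof)[cl, "mrna"])
  }
})

test_that("a zero-variance property is excluded from PCH with a warning", {
  x <- seq(20, 100, length.out = 30)
  df <- makeCanonicalDf(x, 0.6 * x + 141)       # all proteins in C2
  df$transcription_rate <- 1.7                  # constant
  ds <- ProteinDataset(df)
  asg <- suppressWarnings(assignClusters(ds, RegressionFit(0.6, 141)))
  expect_warning(prof <- correlationProfile(ds, asg), "zero variance")
  expect_false(any(pchMask(prof)[, "transcription"]))
})
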