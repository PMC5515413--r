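.fixtureClassifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generateDataset(liverlikePreset(seed = 23))
      asg <- assignClusters(ds, fitGlobalRegression(ds))
      clf <- trainClassifier(ds, asg, classifierSpec(maxEpochs = 200,
                                                     seed = 2))
      cache <<- list(ds = ds, asg = asg, clf = clf)
    }
    cache
  }
})

test_that("class probabilities live on the simplex", {
  fx <- .fixtureClassifier()
  pred <- classifyProteins(fx$clf, fx$ds)
  p <- as.matrix(pred[paste0("p_", c("C1", "C2", "C3"))])
  expect_true(all(p >= 0))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  raw <- as.matrix(pred[paste0("raw_p_", c("C1", "C2", "C3"))])
  expect_true(all(abs(rowSums(raw) - 1) < 1e-9))
})

test_that("prior reweighting multiplies raw probabilities and renormalizes", {
  fx <- .fixtureClassifier()
  pred <- classifyProteins(fx$clf, fx$ds, usePriors = TRUE)
  raw <- as.matrix(pred[paste0("raw_p_", c("C1", "C2", "C3"))])
  q <- sweep(raw, 2, fx$clf@priors, `*`)
  q <- q / rowSums(q)
  expect_equal(unname(as.matrix(pred[paste0("p_", c("C1", "C2", "C3"))])),
               unname(q), tolerance = 1e-12)
  # a protein the network finds uninformative is routed by the priors:
  # with uniform raw output the reweighted argmax is the largest prior
  u <- rep(1 / 3, 3)
  expect_equal(which.max(u * fx$clf@priors), which.max(fx$clf@priors))
})

test_that("training is deterministic under a fixed seed", {
  fx <- .fixtureClassifier()
  clf2 <- trainClassifier(fx$ds, fx$asg, classifierSpec(maxEpochs = 200,
                                                        seed = 2))
  expect_identical(fx$clf@fit$wts, clf2@fit$wts)
  expect_identical(classifyProteins(fx$clf, fx$ds),
                   classifyProteins(clf2, fx$ds))
})

test_that("a class below the minimum size is refused by name", {
  fx <- .fixtureClassifier()
  keep <- names(clusterLabels(fx$asg))[clusterLabels(fx$asg) != "C2"][1:40]
  ds2 <- fx$ds[c(keep, names(clusterLabels(fx$asg))[
    clusterLabels(fx$asg) == "C2"][1:3])]
  asg2 <- assignClusters(ds2, referenceFit(fx$asg))
  expect_error(trainClassifier(ds2, asg2), "C2")
})

test_that("missing features are a contract error naming the feature", {
  fx <- .fixtureClassifier()
  feats <- transformFeatures(fx$ds)[1:3, ]
  feats[2, "mrna"] <- NA
  expect_error(classifyProteins(fx$clf, feats), "mrna")
})

test_that("hidden-unit selection returns a single candidate unchanged", {
  fx <- .fixtureClassifier()
  expect_equal(as.integer(selectHiddenUnits(fx$ds, fx$asg,
                                            candidates = 24L)), 24L)
})

test_that("hidden-unit selection cross-validates and breaks ties small", {
  ds <- generateDataset(generatorConfig(
    nProteins = 240, seed = 31, noiseSd = 0,
    bandOffsets = list(C1 = c(0.60, 1.00), C2 = c(-0.05, 0.05),
                       C3 = c(-0.70, -0.55)),
    propertyCorrelations = c(abundance = 0.97, transcription = 0.95,
                             translation = 0.95)))
  asg <- assignClusters(ds, RegressionFit(0.60863, 141.28857))
  pick <- selectHiddenUnits(ds, asg, candidates = c(6L, 12L),
                            spec = classifierSpec(maxEpochs = 120, seed = 4))
  acc <- attr(pick, "accuracy")
  expect_length(acc, 2L)
  expect_true(as.integer(pick) %in% c(6L, 12L))
  # the tie rule prefers the smaller count at equal accuracy
  expect_equal(as.integer(pick),
               c(6L, 12L)[order(-acc, c(6L, 12L))][1])
})
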