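## a small trained model fixture shared by several blocks
.fixtureModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generateDataset(liverlikePreset(seed = 6))
      asg <- assignClusters(ds, fitGlobalRegression(ds))
      m <- trainClusterModel(ds, asg, "C2",
                             gaCfg = gaConfig(generations = 40, seed = 3))
      cache <<- list(ds = ds, asg = asg, model = m)
    }
    cache
  }
})

test_that("predictLinear is the masked linear combination plus intercept", {
  fx <- .fixtureModel()
  m <- fx$model
  # all-zero weights reduce to the intercept
  m0 <- m
  m0@weights[] <- 0
  m0@activeMask <- rep(FALSE, 7)
  feat <- setNames(rep(3, 7), halflifeFeatures())
  expect_equal(predictLinear(feat, m0), intercept(m))
  # hand arithmetic: 0.6 x 100 + 141 = 201
  m1 <- m0
  m1@weights["cell_halflife"] <- 0.6
  m1@activeMask[1] <- TRUE
  m1@interceptWc <- 141
  feat <- setNames(c(100, 0, 0, 0, 0, 0, 0), halflifeFeatures())
  expect_equal(predictLinear(feat, m1), 201)
  expect_error(predictLinear(rep(1, 6), m1), "7 columns")
})

test_that("a PCH model's prediction is invariant to masked features", {
  fx <- .fixtureModel()
  prof <- correlationProfile(fx$ds, fx$asg)
  m <- trainClusterModel(fx$ds, fx$asg, "C2", mode = "PCH", profile = prof,
                         gaCfg = gaConfig(generations = 10, seed = 5))
  expect_gt(sum(!m@activeMask), 0)  # the default generator has anti-
  masked <- which(!m@activeMask)[1] # correlated features, so some are masked
  feat <- setNames(runif(7, 1, 5), halflifeFeatures())
  p1 <- predictLinear(feat, m)
  feat[masked] <- 1e6
  expect_equal(predictLinear(feat, m), p1)
})

test_that("the objective matches hand arithmetic and a naive-loop oracle", {
  # single protein, Y = 100, prediction 110 -> 0.1
  expect_equal(relativeErrorObjective(1, matrix(10), 100, 100), 0.1)
  # weights reproducing every target exactly give 0
  F <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  w <- c(0.5, 0.25)
  y <- as.numeric(F %*% w) + 50
  expect_equal(relativeErrorObjective(w, F, y, 50), 0)
  # naive-loop oracle on random input
  set.seed(71)
  F <- matrix(runif(35, 0, 10), 5, 7)
  w <- runif(7)
  y <- runif(5, 50, 300)
  loop <- 0
  for (i in 1:5) loop <- loop + abs(sum(F[i, ] * w) + 120 - y[i]) / y[i]
  expect_equal(relativeErrorObjective(w, F, y, 120, "sum"), loop,
               tolerance = 1e-12)
  expect_equal(relativeErrorObjective(w, F, y, 120), loop / 5,
               tolerance = 1e-12)
  expect_error(relativeErrorObjective(w, F, c(y[-5], -1), 120), "> 0")
})

test_that("the training split is a disjoint, exhaustive, uniform third", {
  ids <- sprintf("P%02d", 1:9)
  sp <- splitTraining(ids, seed = 4)
  expect_length(sp$train, 3L)
  expect_length(sp$eval, 6L)
  expect_length(intersect(sp$train, sp$eval), 0L)
  expect_setequal(c(sp$train, sp$eval), ids)
  expect_identical(sp, splitTraining(ids, seed = 4))  # same seed, same split
  expect_error(splitTraining(ids[1:5]), "too small")

  # over many reseeded splits each member trains about a third of the time
  ids <- sprintf("P%02d", 1:30)
  freq <- setNames(numeric(30), ids)
  for (s in 1:500) {
    tr <- splitTraining(ids, seed = s)$train
    freq[tr] <- freq[tr] + 1
  }
  # joint check over 30 members needs the wider per-member band
  lo <- qbinom(0.0005, 500, 1 / 3); hi <- qbinom(0.9995, 500, 1 / 3)
  expect_true(all(freq >= lo & freq <= hi))
  expect_lt(abs(mean(freq) / 500 - 1 / 3), 0.01)
})

test_that("percentage error follows its definition and is scale-invariant", {
  expect_equal(percentageError(100, 100), 0)
  expect_equal(percentageError(120, 100), 0.2)
  expect_equal(percentageError(2 * 137, 2 * 92),
               percentageError(137, 92))
  expect_error(percentageError(10, 0), "> 0")
})

test_that("the PE table counts thresholds correctly", {
  fx <- .fixtureModel()
  # perfect predictor control: predict the observed value itself
  m <- fx$model
  tab <- peTable(evaluatePETable(list(m), fx$asg, fx$ds))
  expect_true(all(diff(as.numeric(tab[1, c("pe_5", "pe_10", "pe_20",
                                           "pe_30")])) >= 0))
  # hand-computed example: PEs {0.03, 0.08, 0.15, 0.5}
  pes <- c(0.03, 0.08, 0.15, 0.5)
  fr <- sapply(c(0.05, 0.10, 0.20, 0.30), function(t) mean(pes <= t))
  expect_equal(fr, c(0.25, 0.50, 0.75, 0.75))
})

test_that("GA best objective is non-increasing and seed-reproducible", {
  fx <- .fixtureModel()
  tr <- objectiveTrace(fx$model)
  expect_true(all(diff(tr) <= 1e-12))
  m2 <- trainClusterModel(fx$ds, fx$asg, "C2",
                          gaCfg = gaConfig(generations = 40, seed = 3))
  expect_identical(modelWeights(fx$model), modelWeights(m2))
  expect_identical(trainIds(fx$model), trainIds(m2))
  expect_equal(fx$model@objective, m2@objective)
})

test_that("trained weights stay in the open box with masked weights at 0", {
  fx <- .fixtureModel()
  w <- modelWeights(fx$model)
  expect_true(all(w > 0 & w < 1))
  prof <- correlationProfile(fx$ds, fx$asg)
  m <- trainClusterModel(fx$ds, fx$asg, "C3", mode = "PCH", profile = prof,
                         gaCfg = gaConfig(generations = 10, seed = 9))
  expect_true(all(modelWeights(m)[!m@activeMask] == 0))
  act <- modelWeights(m)[m@activeMask]
  expect_true(all(act > 0 & act < 1))
})

test_that("GA recovers the generating cell-half-life weight on clean data", {
  # cluster generated exactly as Y = 0.6 X + w_c, all other weights absent
  set.seed(55)
  x <- runif(60, 20, 150)
  df <- makeCanonicalDf(x, 0.6 * x + 141)
  df$abundance <- runif(60, 1e3, 1e5)  # uninformative variation
  ds <- ProteinDataset(df)
  asg <- suppressWarnings(assignClusters(ds, RegressionFit(0.6, 141)))
  prof <- suppressWarnings(correlationProfile(ds, asg))
  mask <- pchMask(prof)
  mask["C2", ] <- c(TRUE, rep(FALSE, 6))
  prof@pchMask <- mask
  m <- trainClusterModel(ds, asg, "C2", mode = "PCH", profile = prof,
                         interceptWc = 141,
                         gaCfg = gaConfig(generations = 150, seed = 12))
  expect_lt(abs(modelWeights(m)[["cell_halflife"]] - 0.6), 0.02)
})
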