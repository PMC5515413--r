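test_that("identical seed and config give a byte-identical dataset", {
  cfg <- generatorConfig(nProteins = 200, seed = 42, uncommonFraction = 0.2,
                         shorterFraction = 0.1)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(records(a), records(b))
  expect_identical(truthTable(a), truthTable(b))
})

test_that("noise-free central-band generation satisfies the band bound", {
  cfg <- generatorConfig(nProteins = 300, seed = 5, noiseSd = 0,
                         bandFractions = c(0, 1, 0))
  ds <- generateDataset(cfg)
  df <- records(ds)
  pred <- cfg$slopeTrue * df$cell_halflife_h + cfg$interceptTrue
  expect_true(all(abs(df$tissue_halflife_h - pred) / pred <= 0.10))
})

test_that("configured property correlations are realised", {
  cfg <- generatorConfig(nProteins = 2000, seed = 11,
                         propertyCorrelations = c(abundance = 0.5,
                                                  mrna = -0.4))
  ds <- generateDataset(cfg)
  df <- records(ds)
  # recomputed with the textbook formula on the emitted (log-scale) table
  rAb <- pearsonOracle(log(df$abundance), log(df$tissue_halflife_h))
  rMr <- pearsonOracle(log(df$mrna_level), log(df$tissue_halflife_h))
  expect_lt(abs(rAb - 0.5), 0.07)
  expect_lt(abs(rMr + 0.4), 0.07)
})

test_that("uncommon records appear at the configured rate", {
  ds <- generateDataset(generatorConfig(nProteins = 1000, seed = 8,
                                        uncommonFraction = 0.9))
  k <- sum(!isCommon(ds))
  # binomial 99% interval around 900, computed independently
  expect_gte(k, qbinom(0.005, 1000, 0.9))
  expect_lte(k, qbinom(0.995, 1000, 0.9))
  # truth still carries the withheld tissue half-lives
  expect_false(anyNA(truthTable(ds)$tissue_halflife_true))
})

test_that("an infeasible correlation target is rejected before sampling", {
  expect_error(generatorConfig(propertyCorrelations = c(abundance = 1.2)),
               "positive-semidefinite")
})

test_that("all emitted raw properties are strictly positive", {
  ds <- generateDataset(generatorConfig(nProteins = 500, seed = 13,
                                        shorterFraction = 0.2))
  df <- records(ds)
  for (col in c("cell_halflife_h", "length_aa", "abundance", "mrna_level",
                "transcription_rate", "translation_rate"))
    expect_true(all(df[[col]] > 0), label = col)
  expect_true(all(df$disorder_count >= 0))
  expect_true(all(df$tissue_halflife_h > 0, na.rm = TRUE))
})

test_that("the shorter-in-tissue subgroup has the requested structure", {
  cfg <- generatorConfig(nProteins = 2000, seed = 21, shorterFraction = 0.15,
                         longCellFraction = 0.6)
  ds <- generateDataset(cfg)
  tr <- truthTable(ds)
  df <- records(ds)
  expect_true(all(df$tissue_halflife_h[tr$shorter] <
                    df$cell_halflife_h[tr$shorter]))
  expect_true(all(df$cell_halflife_h[tr$long_cell] > 200))
  pShort <- mean(tr$shorter)
  expect_gt(pShort, 0.15 - 3 * sqrt(0.15 * 0.85 / 2000))
  expect_lt(pShort, 0.15 + 3 * sqrt(0.15 * 0.85 / 2000))
  pLong <- mean(tr$long_cell[tr$shorter])
  expect_lt(abs(pLong - 0.6), 3 * sqrt(0.6 * 0.4 / sum(tr$shorter)))
})

test_that("the liver-like preset encodes the observed cohort structure", {
  cfg <- liverlikePreset(seed = 2)
  expect_equal(cfg$nProteins, 366L)
  expect_equal(unname(cfg$bandFractions), c(130, 67, 169) / 366)
  expect_equal(cfg$slopeTrue, 0.60863)
  expect_equal(cfg$interceptTrue, 141.28857)
  # band-offset mixture is mean-centred on the generating line
  mids <- sapply(cfg$bandOffsets, mean)
  expect_lt(abs(sum(cfg$bandFractions * mids)), 1e-6)
})
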