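# Independent oracles and small fixture builders used across the suite.

# closed-form OLS via the normal equations (independent of stats::lm)
olsOracle <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# textbook Pearson correlation
pearsonOracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# hand-coded residual band rule (boundary |d| == width belongs to C2)
bandRuleOracle <- function(d, width = 0.10) {
  ifelse(d > width, "C1", ifelse(d < -width, "C3", "C2"))
}

# exhaustive grid search over two free weights at the given step
gridSearchOracle <- function(features2, targets, interceptWc, step = 0.01) {
  grid <- seq(step, 1 - step, by = step)
  best <- Inf
  for (w1 in grid) {
    pred1 <- features2[, 1] * w1 + interceptWc
    for (w2 in grid) {
      obj <- mean(abs(pred1 + features2[, 2] * w2 - targets) / targets)
      if (obj < best) best <- obj
    }
  }
  best
}

# canonical data.frame with prescribed half-lives and benign aux properties
makeCanonicalDf <- function(cell, tissue,
                            ids = sprintf("P%03d", seq_along(cell))) {
  n <- length(cell)
  data.frame(protein_id = ids, cell_halflife_h = cell,
             tissue_halflife_h = tissue,
             length_aa = 300L + 10L * seq_len(n),
             abundance = 1e4 * seq_len(n),
             disorder_count = rep(c(0L, 2L), length.out = n),
             mrna_level = 5 + 0.3 * seq_len(n),
             transcription_rate = 1.2 + 0.05 * seq_len(n),
             translation_rate = 20 + seq_len(n), stringsAsFactors = FALSE)
}

makeLineDataset <- function(cell, slope, intercept, ...) {
  ProteinDataset(makeCanonicalDf(cell, slope * cell + intercept, ...))
}
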