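#' @include synthetic.R
NULL

.olsFit <- function(x, y, scope) {
  if (length(x) < 3L)
    stop("need at least 3 proteins with both half-lives (", scope,
         " has ", length(x), ")")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  new("RegressionFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      n = length(x),
      pearsonR = unname(stats::cor(x, y)),
      pValue = unname(sm$coefficients[2, 4]),
      scope = scope)
}

#' Fit the global tissue~cell half-life regression
#'
#' Ordinary least squares of tissue half-life on cell-culture half-life over
#' all common proteins (both half-lives in raw hours by default). This is
#' the reference line the residual bands are measured from.
#'
#' @param dataset A \linkS4class{ProteinDataset} with at least 3 common
#'   proteins.
#' @param config A \code{\link{transformConfig}}; with \code{logHalflives}
#'   the regression is fitted on the log scale instead.
#' @return A \linkS4class{RegressionFit}.
#' @export
#' @examples
#' ds <- generateDataset(liverlikePreset(seed = 3))
#' fitGlobalRegression(ds)
fitGlobalRegression <- function(dataset, config = transformConfig()) {
  df <- records(dataset)
  ok <- !is.na(df$tissue_halflife_h)
  x <- df$cell_halflife_h[ok]; y <- df$tissue_halflife_h[ok]
  if (config$logHalflives) { x <- log(x); y <- log(y) }
  .olsFit(x, y, "global")
}

#' Relative deviation from a regression line
#'
#' d = (Y - (m X + w)) / (m X + w): the signed relative distance of the
#' observed tissue half-life from the line's fitted value. Positive d lies
#' above the line. The denominator is the fitted value by default; set
#' \code{denominator = "observed"} to divide by Y instead.
#'
#' @param dataset A \linkS4class{ProteinDataset} (common proteins only are
#'   meaningful), or a data.frame in canonical layout.
#' @param fit A \linkS4class{RegressionFit}.
#' @param denominator "fitted" (default) or "observed".
#' @return Named numeric vector of deviations for the common proteins.
#' @export
relativeDeviation <- function(dataset, fit,
                              denominator = c("fitted", "observed")) {
  denominator <- match.arg(denominator)
  df <- if (is(dataset, "ProteinDataset")) records(dataset)
        else as.data.frame(dataset)
  ok <- !is.na(df$tissue_halflife_h)
  x <- df$cell_halflife_h[ok]; y <- df$tissue_halflife_h[ok]
  pred <- slope(fit) * x + intercept(fit)
  if (any(pred <= 0))
    stop("regression line predicts a non-positive half-life; ",
         "relative deviation undefined")
  den <- if (denominator == "fitted") pred else y
  stats::setNames((y - pred) / den, df$protein_id[ok])
}

#' Partition common proteins into the three residual bands
#'
#' Labels every common protein C1, C2 or C3 by its relative deviation from
#' the reference line: C1 if d > bandWidth, C3 if d < -bandWidth, C2
#' otherwise (the boundary |d| = bandWidth belongs to C2). Also computes the
#' within-band (C2) Pearson correlation between the two half-lives — the
#' strongly-correlated core the method exploits.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param fit A \linkS4class{RegressionFit} (typically from
#'   \code{\link{fitGlobalRegression}}).
#' @param bandWidth relative half-width of the central band (default 0.10).
#' @param denominator see \code{\link{relativeDeviation}}.
#' @return A \linkS4class{ClusterAssignment}.
#' @export
#' @examples
#' ds <- generateDataset(liverlikePreset(seed = 3))
#' assignClusters(ds, fitGlobalRegression(ds))
assignClusters <- function(dataset, fit, bandWidth = 0.10,
                           denominator = c("fitted", "observed")) {
  stopifnot(bandWidth > 0)
  d <- relativeDeviation(dataset, fit, denominator = match.arg(denominator))
  lab <- ifelse(d > bandWidth, "C1", ifelse(d < -bandWidth, "C3", "C2"))
  lab <- factor(lab, levels = .clusterLevels)
  empty <- .clusterLevels[tabulate(lab, 3) == 0]
  if (length(empty) > 0)
    warning("empty cluster(s): ", paste(empty, collapse = ", "))
  df <- records(dataset)
  common <- df[!is.na(df$tissue_halflife_h), ]
  inC2 <- lab == "C2"
  wbr <- if (sum(inC2) >= 3 &&
             stats::sd(common$cell_halflife_h[inC2]) > 0 &&
             stats::sd(common$tissue_halflife_h[inC2]) > 0)
    stats::cor(common$cell_halflife_h[inC2], common$tissue_halflife_h[inC2])
  else NA_real_
  new("ClusterAssignment", ids = names(d), labels = lab,
      deviations = unname(d), bandWidth = bandWidth, referenceFit = fit,
      withinBandR = wbr)
}

#' Fit one cluster's tissue~cell regression
#'
#' OLS restricted to the members of a single band. The intercept of this fit
#' is the fixed intercept (w_c) of the cluster's multivariate predictor.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param cluster "C1", "C2" or "C3".
#' @return A \linkS4class{RegressionFit} with \code{scope} set to the
#'   cluster.
#' @export
fitClusterRegression <- function(dataset, assignment,
                                 cluster = c("C1", "C2", "C3")) {
  cluster <- match.arg(cluster)
  ids <- assignment@ids[assignment@labels == cluster]
  df <- records(dataset)
  sel <- df[df$protein_id %in% ids, ]
  .olsFit(sel$cell_halflife_h, sel$tissue_halflife_h, cluster)
}

#' Per-cluster property correlations and the PCH mask
#'
#' Pearson correlation of each transformed model feature with the tissue
#' half-life, computed within each cluster. The PCH (positively-correlated
#' half-life properties) mask marks, per cluster, the features with strictly
#' positive correlation; those are the only features allowed a nonzero
#' weight when a cluster model is trained in PCH mode. A feature with zero
#' variance inside a cluster has undefined correlation and is excluded from
#' PCH with a warning.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param config A \code{\link{transformConfig}}.
#' @param method "pearson" (default, used for PCH) or "spearman".
#' @return A \linkS4class{CorrelationProfile}.
#' @export
correlationProfile <- function(dataset, assignment,
                               config = transformConfig(),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  feats <- transformFeatures(dataset, config)
  df <- records(dataset)
  y <- stats::setNames(transformResponse(df$tissue_halflife_h, config),
                       df$protein_id)
  labs <- clusterLabels(assignment)
  cors <- matrix(NA_real_, 3, 7,
                 dimnames = list(.clusterLevels, halflifeFeatures()))
  for (cl in .clusterLevels) {
    ids <- names(labs)[labs == cl]
    if (length(ids) < 3) next
    fm <- feats[ids, , drop = FALSE]
    for (f in halflifeFeatures()) {
      if (stats::sd(fm[, f]) == 0) {
        warning("feature '", f, "' has zero variance in ", cl,
                "; excluded from PCH")
      } else {
        cors[cl, f] <- stats::cor(fm[, f], y[ids], method = method)
      }
    }
  }
  mask <- !is.na(cors) & cors > 0
  new("CorrelationProfile", correlations = cors, pchMask = mask)
}
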