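#' @include AllGenerics.R
NULL

## canonical column and feature vocabulary -------------------------------

#' Canonical columns and feature order
#'
#' The canonical tabular layout is one row per protein with columns
#' \code{protein_id}, \code{cell_halflife_h}, \code{tissue_halflife_h},
#' \code{length_aa}, \code{abundance}, \code{disorder_count},
#' \code{mrna_level}, \code{transcription_rate}, \code{translation_rate}.
#' Half-lives are in hours; \code{tissue_halflife_h} is \code{NA} for
#' "uncommon" proteins quantified only in cell culture. The fixed feature
#' order used by every model in the package is cell half-life, protein
#' length, abundance, disordered-segment count, mRNA level, transcription
#' rate, translation rate.
#'
#' @return \code{halflifeFeatures()} returns the 7 feature names in canonical
#'   order; \code{canonicalColumns()} returns the 9 canonical column names.
#' @export
#' @examples
#' halflifeFeatures()
halflifeFeatures <- function() {
  c("cell_halflife", "length", "abundance", "disorder",
    "mrna", "transcription", "translation")
}

#' @rdname halflifeFeatures
#' @export
canonicalColumns <- function() {
  c("protein_id", "cell_halflife_h", "tissue_halflife_h", "length_aa",
    "abundance", "disorder_count", "mrna_level", "transcription_rate",
    "translation_rate")
}

## column holding each feature's raw value
.featureColumn <- c(
  cell_halflife = "cell_halflife_h", length = "length_aa",
  abundance = "abundance", disorder = "disorder_count",
  mrna = "mrna_level", transcription = "transcription_rate",
  translation = "translation_rate")

.clusterLevels <- c("C1", "C2", "C3")

## ProteinDataset --------------------------------------------------------

#' ProteinDataset: per-protein half-lives and cellular properties
#'
#' Container for a tabular half-life dataset: one row per protein holding the
#' cell-culture half-life (hours), the tissue half-life (hours, \code{NA} for
#' proteins observed only in cell culture — the "uncommon" proteins), and the
#' auxiliary cellular properties used as model features (length, abundance,
#' intrinsically-disordered-segment count, mRNA level, transcription and
#' translation rates).
#'
#' @slot records data.frame in the canonical column layout
#'   (see \code{\link{canonicalColumns}}).
#' @slot provenance free-text label describing where the data came from.
#' @slot metadata list of processing notes (e.g. rejected input rows).
#'
#' @seealso \code{\link{readProteinDataset}}, \code{\link{generateDataset}}
#' @export
setClass("ProteinDataset",
  representation(records = "data.frame", provenance = "character",
                 metadata = "list"),
  prototype(provenance = NA_character_, metadata = list()))

setValidity("ProteinDataset", function(object) {
  df <- object@records
  missing <- setdiff(canonicalColumns(), names(df))
  if (length(missing) > 0)
    return(paste("missing canonical columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(df$protein_id))
    return("protein_id values must be unique")
  pos <- c("cell_halflife_h", "length_aa", "abundance", "mrna_level",
           "transcription_rate", "translation_rate")
  for (col in pos) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0))
      return(paste0("column '", col, "' must be strictly positive"))
  }
  if (any(!is.na(df$tissue_halflife_h) & df$tissue_halflife_h <= 0))
    return("tissue_halflife_h must be strictly positive when present")
  if (any(!is.na(df$disorder_count) & df$disorder_count < 0))
    return("disorder_count must be nonnegative")
  TRUE
})

#' Construct a ProteinDataset
#'
#' @param records data.frame with the canonical columns.
#' @param provenance free-text provenance label.
#' @param metadata list of processing notes.
#' @return A \linkS4class{ProteinDataset}.
#' @export
#' @examples
#' df <- data.frame(protein_id = c("P1", "P2"),
#'   cell_halflife_h = c(20, 45), tissue_halflife_h = c(110, NA),
#'   length_aa = c(300L, 512L), abundance = c(1e5, 3e4),
#'   disorder_count = c(2L, 0L), mrna_level = c(12, 7),
#'   transcription_rate = c(1.5, 0.8), translation_rate = c(30, 12))
#' ProteinDataset(df, provenance = "example")
ProteinDataset <- function(records, provenance = NA_character_,
                           metadata = list()) {
  records <- as.data.frame(records)[, canonicalColumns()]
  rownames(records) <- NULL
  new("ProteinDataset", records = records,
      provenance = as.character(provenance), metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("records", "ProteinDataset", function(x, ...) x@records)

#' @rdname accessors
#' @export
setMethod("proteinIds", "ProteinDataset", function(x, ...)
  x@records$protein_id)

#' @rdname accessors
#' @export
setMethod("isCommon", "ProteinDataset", function(x, ...)
  !is.na(x@records$tissue_halflife_h))

#' @rdname accessors
#' @export
setMethod("provenance", "ProteinDataset", function(x, ...) x@provenance)

#' @export
setMethod("length", "ProteinDataset", function(x) nrow(x@records))

#' Subset a ProteinDataset by row index or protein id
#'
#' @param x A \linkS4class{ProteinDataset}.
#' @param i integer, logical or character (protein id) index.
#' @param j,...,drop ignored.
#' @return A \linkS4class{ProteinDataset} with the selected records.
#' @export
setMethod("[", "ProteinDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$protein_id)
  initialize(x, records = {
    df <- x@records[i, , drop = FALSE]; rownames(df) <- NULL; df
  })
})

setMethod("show", "ProteinDataset", function(object) {
  n <- nrow(object@records)
  nc <- sum(isCommon(object))
  cat("ProteinDataset with", n, "proteins (", nc, "common,",
      n - nc, "uncommon )\n")
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  if (length(object@metadata$rejected_rows))
    cat("  rejected input rows:", nrow(object@metadata$rejected_rows), "\n")
})

## SyntheticDataset ------------------------------------------------------

#' SyntheticDataset: a generated dataset plus its generating truth
#'
#' Extends \linkS4class{ProteinDataset} with the generator's ground truth so
#' downstream stages can be tested against known labels and parameters.
#'
#' @slot truth data.frame with \code{protein_id}, \code{true_band} (C1/C2/C3),
#'   \code{delta} (relative offset from the generating line),
#'   \code{tissue_halflife_true} (hours; kept even for uncommon records),
#'   \code{shorter} and \code{long_cell} subgroup flags.
#' @slot generatorConfig the \code{\link{generatorConfig}} list used.
#' @export
setClass("SyntheticDataset", contains = "ProteinDataset",
  representation(truth = "data.frame", generatorConfig = "list"))

#' @rdname accessors
#' @export
setMethod("truthTable", "SyntheticDataset", function(x, ...) x@truth)

setMethod("show", "SyntheticDataset", function(object) {
  callNextMethod()
  cat("  truth: bands", paste(sprintf("%s=%d", .clusterLevels,
      tabulate(factor(object@truth$true_band, .clusterLevels), 3)),
      collapse = " "), "\n")
})

## RegressionFit ---------------------------------------------------------

#' RegressionFit: a bivariate tissue~cell half-life regression
#'
#' Ordinary-least-squares fit of tissue half-life on cell-culture half-life
#' (both in raw hours by default), either on the full common set (the global
#' line the residual bands are drawn around) or restricted to one cluster
#' (whose intercept becomes the fixed intercept of that cluster's
#' multivariate model).
#'
#' @slot slope dimensionless regression coefficient.
#' @slot intercept hours.
#' @slot n number of points used.
#' @slot pearsonR Pearson correlation of the fitted points.
#' @slot pValue two-sided p-value for slope != 0 (t-statistic of the OLS
#'   slope); reported for reference, never used for decisions.
#' @slot scope "global" or the cluster label.
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", n = "integer",
                 pearsonR = "numeric", pValue = "numeric", scope = "character"),
  prototype(scope = "global", pValue = NA_real_))

setValidity("RegressionFit", function(object) {
  if (!is.na(object@pearsonR) &&
      (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12))
    return("pearsonR must lie in [-1, 1]")
  if (!is.na(object@pValue) && object@n < 3L)
    return("a p-value requires n >= 3")
  TRUE
})

#' Construct a RegressionFit directly from known parameters
#'
#' Mostly useful to evaluate the band rule against a known generating line.
#'
#' @param slope,intercept line parameters (intercept in hours).
#' @param n number of supporting points (0 for a purely theoretical line).
#' @param pearsonR,pValue optional diagnostics.
#' @param scope "global" or a cluster label.
#' @return A \linkS4class{RegressionFit}.
#' @export
RegressionFit <- function(slope, intercept, n = 0L, pearsonR = NA_real_,
                          pValue = NA_real_, scope = "global") {
  new("RegressionFit", slope = as.numeric(slope),
      intercept = as.numeric(intercept), n = as.integer(n),
      pearsonR = as.numeric(pearsonR), pValue = as.numeric(pValue),
      scope = scope)
}

#' @rdname accessors
#' @export
setMethod("slope", "RegressionFit", function(object, ...) object@slope)

#' @rdname accessors
#' @export
setMethod("intercept", "RegressionFit", function(object, ...) object@intercept)

#' @rdname accessors
#' @export
setMethod("pearsonR", "RegressionFit", function(object, ...) object@pearsonR)

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit (%s): slope %.5f, intercept %.5f h, n = %d\n",
              object@scope, object@slope, object@intercept, object@n))
  cat(sprintf("  Pearson r = %.4f, slope p-value = %.3g\n",
              object@pearsonR, object@pValue))
})

## ClusterAssignment -----------------------------------------------------

#' ClusterAssignment: the three residual-band clusters
#'
#' Partition of the common proteins by relative deviation from a reference
#' regression line: C1 above the band (deviation > band width), C2 within it
#' (|deviation| <= band width, inclusive at the boundary), C3 below it.
#'
#' @slot ids protein ids of the common proteins, in dataset order.
#' @slot labels factor with levels C1, C2, C3.
#' @slot deviations per-protein relative deviation from the reference line.
#' @slot bandWidth the half-width of the central band (default 0.10).
#' @slot referenceFit the \linkS4class{RegressionFit} used as the line.
#' @slot withinBandR Pearson correlation of tissue vs cell half-life inside
#'   C2 (NA when C2 has fewer than 3 members).
#' @export
setClass("ClusterAssignment",
  representation(ids = "character", labels = "factor", deviations = "numeric",
                 bandWidth = "numeric", referenceFit = "RegressionFit",
                 withinBandR = "numeric"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@ids) != length(object@labels) ||
      length(object@ids) != length(object@deviations))
    return("ids, labels and deviations must have equal length")
  if (!identical(levels(object@labels), .clusterLevels))
    return("labels must be a factor with levels C1, C2, C3")
  if (anyNA(object@labels))
    return("every common protein must carry a cluster label")
  d <- object@deviations; b <- object@bandWidth; l <- as.character(object@labels)
  ok <- ifelse(d > b, l == "C1", ifelse(d < -b, l == "C3", l == "C2"))
  if (!all(ok))
    return("labels inconsistent with deviations and bandWidth")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x, ...) {
  stats::setNames(x@labels, x@ids)
})

#' @rdname accessors
#' @export
setMethod("deviations", "ClusterAssignment", function(x, ...)
  stats::setNames(x@deviations, x@ids))

#' @rdname accessors
#' @export
setMethod("bandWidth", "ClusterAssignment", function(x, ...) x@bandWidth)

#' @rdname accessors
#' @export
setMethod("referenceFit", "ClusterAssignment", function(x, ...)
  x@referenceFit)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterAssignment", function(x, ...)
  table(x@labels))

setMethod("show", "ClusterAssignment", function(object) {
  sz <- table(object@labels)
  cat(sprintf(
    "ClusterAssignment: %d common proteins, band width %.2f\n",
    length(object@ids), object@bandWidth))
  cat(sprintf("  C1 (above): %d   C2 (within): %d   C3 (below): %d\n",
              sz["C1"], sz["C2"], sz["C3"]))
  if (!is.na(object@withinBandR))
    cat(sprintf("  within-band (C2) Pearson r = %.4f\n", object@withinBandR))
})

## CorrelationProfile ----------------------------------------------------

#' CorrelationProfile: per-cluster property/half-life correlations
#'
#' Pearson correlation of each (transformed) model feature with the tissue
#' half-life, per cluster, and the derived PCH mask: a feature belongs to the
#' positively-correlated set (PCH) of a cluster iff its correlation there is
#' strictly positive. Features with undefined correlation (zero variance) are
#' excluded from PCH.
#'
#' @slot correlations clusters x features numeric matrix.
#' @slot pchMask clusters x features logical matrix.
#' @export
setClass("CorrelationProfile",
  representation(correlations = "matrix", pchMask = "matrix"))

setValidity("CorrelationProfile", function(object) {
  if (!identical(colnames(object@correlations), halflifeFeatures()))
    return("correlations must have one column per canonical feature")
  if (!identical(dim(object@correlations), dim(object@pchMask)))
    return("correlations and pchMask must have identical shape")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("pchMask", "CorrelationProfile", function(x, ...) x@pchMask)

setMethod("show", "CorrelationProfile", function(object) {
  cat("CorrelationProfile (feature vs tissue half-life, Pearson):\n")
  print(round(object@correlations, 3))
  cat("PCH members per cluster:\n")
  for (cl in rownames(object@pchMask))
    cat(" ", cl, ":", paste(colnames(object@pchMask)[object@pchMask[cl, ]],
                            collapse = ", "), "\n")
})

## ClusterModel ----------------------------------------------------------

#' ClusterModel: one cluster's multivariate linear predictor
#'
#' Predicted tissue half-life = sum over features of weight x feature value
#' plus the cluster's fixed intercept (the intercept of that cluster's own
#' tissue~cell regression, never optimised). Active weights are
#' box-constrained to (0, 1) and trained by a genetic algorithm minimising
#' the mean relative prediction error on a random one-third of the cluster;
#' in PCH mode the negatively-correlated features carry weight exactly 0.
#'
#' @slot cluster "C1", "C2" or "C3".
#' @slot weights named numeric 7-vector in canonical feature order.
#' @slot interceptWc hours; fixed from the cluster regression.
#' @slot mode "ACH" (all features) or "PCH" (positively correlated only).
#' @slot activeMask logical 7-vector; FALSE entries have weight exactly 0.
#' @slot trainIds protein ids of the training third.
#' @slot seed RNG seed used for the split and the GA.
#' @slot trace best objective per GA generation (mean relative error).
#' @slot objective final best mean relative error on the training set.
#' @slot objectiveSum the same objective as a raw sum over training proteins.
#' @export
setClass("ClusterModel",
  representation(cluster = "character", weights = "numeric",
                 interceptWc = "numeric", mode = "character",
                 activeMask = "logical", trainIds = "character",
                 seed = "integer", trace = "numeric", objective = "numeric",
                 objectiveSum = "numeric"))

setValidity("ClusterModel", function(object) {
  if (length(object@weights) != 7L ||
      !identical(names(object@weights), halflifeFeatures()))
    return("weights must be a named 7-vector in canonical feature order")
  if (length(object@activeMask) != 7L)
    return("activeMask must have length 7")
  if (any(object@weights[!object@activeMask] != 0))
    return("inactive weights must be exactly 0")
  w <- object@weights[object@activeMask]
  if (length(w) && (any(w <= 0) || any(w >= 1)))
    return("active weights must lie in the open interval (0, 1)")
  if (!object@mode %in% c("ACH", "PCH"))
    return("mode must be ACH or PCH")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("modelWeights", "ClusterModel", function(object, ...)
  object@weights)

#' @rdname accessors
#' @export
setMethod("intercept", "ClusterModel", function(object, ...)
  object@interceptWc)

#' @rdname accessors
#' @export
setMethod("trainIds", "ClusterModel", function(x, ...) x@trainIds)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "ClusterModel", function(x, ...) x@trace)

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel %s (%s): intercept %.3f h, trained on %d proteins\n",
              object@cluster, object@mode, object@interceptWc,
              length(object@trainIds)))
  w <- format(round(object@weights, 4), nsmall = 4)
  cat("  weights:\n")
  for (f in halflifeFeatures()) cat(sprintf("    %-14s %s\n", f, w[f]))
  cat(sprintf("  training mean relative error: %.4f (sum %.3f)\n",
              object@objective, object@objectiveSum))
})

## EvaluationTable -------------------------------------------------------

#' EvaluationTable: held-out percentage-of-error summary
#'
#' For each cluster and feature mode, the fraction of held-out proteins whose
#' predicted tissue half-life falls within 5, 10, 20 and 30 percent of the
#' observed value (percentage of error PE = |predicted - observed| /
#' observed, thresholds applied as PE <= t).
#'
#' @slot table data.frame with columns cluster, mode, n_eval and one column
#'   per threshold (named like "pe_10").
#' @slot thresholds numeric vector of PE thresholds (fractions).
#' @export
setClass("EvaluationTable",
  representation(table = "data.frame", thresholds = "numeric"))

setValidity("EvaluationTable", function(object) {
  cols <- paste0("pe_", round(100 * object@thresholds))
  if (!all(c("cluster", "mode", "n_eval", cols) %in% names(object@table)))
    return("table missing required columns")
  fr <- as.matrix(object@table[, cols, drop = FALSE])
  if (nrow(fr) && (any(fr < -1e-12) || any(fr > 1 + 1e-12)))
    return("PE fractions must lie in [0, 1]")
  if (nrow(fr) && any(apply(fr, 1, function(z) any(diff(z) < -1e-12))))
    return("PE fractions must be nondecreasing in the threshold")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("peTable", "EvaluationTable", function(x, ...) x@table)

setMethod("show", "EvaluationTable", function(object) {
  cat("EvaluationTable (fraction of held-out proteins with PE <= threshold):\n")
  df <- object@table
  cols <- paste0("pe_", round(100 * object@thresholds))
  df[cols] <- lapply(df[cols], function(z) sprintf("%.0f%%", 100 * z))
  print(df, row.names = FALSE)
})

## ClusterClassifier -----------------------------------------------------

#' ClusterClassifier: neural-network router from features to clusters
#'
#' A single-hidden-layer feedforward network (default 24 hidden units,
#' softmax output trained by cross-entropy) mapping the 7 standardized
#' cellular features to cluster membership probabilities. Class priors taken
#' from the observed cluster sizes can reweight the probabilities at
#' classification time.
#'
#' @slot fit the underlying \code{nnet} fit.
#' @slot center,scaleSd per-feature standardization parameters (training set).
#' @slot priors observed cluster frequencies (sum to 1).
#' @slot spec the \code{\link{classifierSpec}} list used.
#' @slot trainAccuracy fraction of training proteins classified into their
#'   own cluster (priors applied as per spec).
#' @export
setClass("ClusterClassifier",
  representation(fit = "ANY", center = "numeric", scaleSd = "numeric",
                 priors = "numeric", spec = "list",
                 trainAccuracy = "numeric"))

setValidity("ClusterClassifier", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-9)
    return("class priors must sum to 1")
  if (length(object@center) != 7L || length(object@scaleSd) != 7L)
    return("standardization parameters must cover the 7 features")
  TRUE
})

setMethod("show", "ClusterClassifier", function(object) {
  cat(sprintf(
    "ClusterClassifier: %d hidden units, training accuracy %.1f%%\n",
    object@spec$hiddenUnits, 100 * object@trainAccuracy))
  cat("  class priors:", paste(sprintf("%s=%.3f", .clusterLevels,
                                       object@priors), collapse = " "), "\n")
})
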