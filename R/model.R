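#' @include ga.R
NULL

#' Predict tissue half-lives with a cluster model
#'
#' Linear combination of the 7 canonical features with the model's weights
#' plus the cluster's fixed intercept:
#' sum_j (weight_j x feature_j) + w_c. Features must be on the model's
#' transform scale (see \code{\link{transformFeatures}}); masked features
#' have weight exactly 0 and cannot influence the prediction.
#'
#' @param features numeric 7-vector or n x 7 matrix in canonical feature
#'   order.
#' @param model A \linkS4class{ClusterModel}.
#' @return Predicted tissue half-life (hours), one value per row.
#' @export
predictLinear <- function(features, model) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
    dimnames = list(NULL, names(features)))
  if (ncol(features) != 7L)
    stop("feature matrix must have 7 columns (canonical feature order)")
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), halflifeFeatures()))
    stop("feature columns must follow the canonical order: ",
         paste(halflifeFeatures(), collapse = ", "))
  as.numeric(features %*% modelWeights(model) + intercept(model))
}

#' Relative-error training objective
#'
#' The training criterion minimised by the genetic algorithm: the relative
#' prediction error |Y_pred - Y| / Y accumulated over the training proteins.
#' The raw criterion is a sum; the default here is the mean (sum divided by
#' the training-set size), which has the identical minimiser and is
#' comparable across clusters of different size. Both are available.
#'
#' @param weights numeric weight vector (one entry per feature column).
#' @param features n x k matrix of transformed features.
#' @param targets observed tissue half-lives (hours), strictly positive.
#' @param interceptWc fixed cluster intercept (hours).
#' @param aggregate "mean" (default) or "sum".
#' @return The objective value (dimensionless).
#' @export
relativeErrorObjective <- function(weights, features, targets, interceptWc,
                                   aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (length(weights) != ncol(features))
    stop("length(weights) must equal ncol(features)")
  if (length(targets) != nrow(features) || length(targets) == 0)
    stop("targets must match the feature rows and be nonempty")
  if (any(targets <= 0)) stop("all target half-lives must be > 0")
  pe <- abs(as.numeric(features %*% weights) + interceptWc - targets) /
    targets
  if (aggregate == "mean") mean(pe) else sum(pe)
}

#' Split a cluster into a training third and an evaluation remainder
#'
#' Uniform sample without replacement of round(N/3) members as the training
#' set; the remaining two-thirds are held out for evaluation.
#'
#' @param ids character vector of cluster member ids (>= 6).
#' @param seed optional RNG seed; when NULL the current RNG stream is used.
#' @return list(train, eval) of disjoint, exhaustive id vectors.
#' @export
splitTraining <- function(ids, seed = NULL) {
  n <- length(ids)
  if (n < 6L) stop("cluster too small to split (", n, " members, need >= 6)")
  if (!is.null(seed)) set.seed(seed)
  train <- sort(sample(ids, round(n / 3)))
  list(train = train, eval = sort(setdiff(ids, train)))
}

#' Train one cluster's predictor with the genetic algorithm
#'
#' Draws the random one-third training split, fixes the intercept at the
#' cluster's own tissue~cell regression intercept, and minimises the mean
#' relative prediction error over the box-constrained (0,1) weights with the
#' GA. In PCH mode, features that are not positively correlated with the
#' tissue half-life in this cluster (per the
#' \code{\link{correlationProfile}}) are held at weight exactly 0.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param cluster "C1", "C2" or "C3".
#' @param mode "ACH" (all features) or "PCH" (positively correlated only).
#' @param profile A \linkS4class{CorrelationProfile}; required for PCH.
#' @param interceptWc optional fixed intercept (hours); defaults to the
#'   intercept of \code{\link{fitClusterRegression}} on this cluster.
#' @param gaCfg A \code{\link{gaConfig}} (its seed fixes split and GA).
#' @param config A \code{\link{transformConfig}}.
#' @return A \linkS4class{ClusterModel}.
#' @export
#' @examples
#' ds <- generateDataset(liverlikePreset(seed = 3))
#' asg <- assignClusters(ds, fitGlobalRegression(ds))
#' m <- trainClusterModel(ds, asg, "C2", gaCfg = gaConfig(generations = 30))
#' m
trainClusterModel <- function(dataset, assignment,
                              cluster = c("C1", "C2", "C3"),
                              mode = c("ACH", "PCH"), profile = NULL,
                              interceptWc = NULL, gaCfg = gaConfig(),
                              config = transformConfig()) {
  cluster <- match.arg(cluster)
  mode <- match.arg(mode)
  stopifnot(inherits(gaCfg, "ga_config"))
  mask <- stats::setNames(rep(TRUE, 7L), halflifeFeatures())
  if (mode == "PCH") {
    if (is.null(profile))
      stop("PCH mode requires a correlationProfile()")
    mask <- pchMask(profile)[cluster, ]
    if (!any(mask)) stop("no positively-correlated feature in ", cluster)
  }
  if (is.null(interceptWc))
    interceptWc <- intercept(fitClusterRegression(dataset, assignment,
                                                  cluster))
  ids <- assignment@ids[assignment@labels == cluster]
  feats <- transformFeatures(dataset, config)[ids, , drop = FALSE]
  df <- records(dataset)
  y <- stats::setNames(transformResponse(df$tissue_halflife_h, config),
                       df$protein_id)[ids]

  set.seed(gaCfg$seed)
  split <- splitTraining(ids, seed = NULL)
  trainF <- feats[split$train, , drop = FALSE]
  trainY <- y[split$train]
  res <- .gaMinimize(trainF[, mask, drop = FALSE], trainY, interceptWc,
                     gaCfg)
  w <- stats::setNames(numeric(7L), halflifeFeatures())
  w[mask] <- res$weights
  new("ClusterModel", cluster = cluster, weights = w,
      interceptWc = interceptWc, mode = mode, activeMask = unname(mask),
      trainIds = split$train, seed = gaCfg$seed, trace = res$trace,
      objective = res$objective,
      objectiveSum = res$objective * length(split$train))
}

#' Percentage of error of a prediction
#'
#' PE = |predicted - observed| / observed: the relative deviation of the
#' predicted tissue half-life from the experimental value. Scale-invariant
#' and defined only for positive observations.
#'
#' @param predicted,observed half-lives in hours (vectorised).
#' @return Dimensionless PE values.
#' @export
#' @examples
#' percentageError(120, 100)  # 0.2
percentageError <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed half-life must be > 0")
  abs(predicted - observed) / observed
}

#' Held-out percentage-of-error table
#'
#' For each trained cluster model, predicts the tissue half-life of that
#' cluster's held-out members (members not in the model's training third)
#' and reports the fraction with PE at or below each threshold.
#'
#' @param models list of \linkS4class{ClusterModel}s.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param thresholds PE thresholds as fractions.
#' @param config A \code{\link{transformConfig}}.
#' @return An \linkS4class{EvaluationTable}.
#' @export
evaluatePETable <- function(models, assignment, dataset,
                            thresholds = c(0.05, 0.10, 0.20, 0.30),
                            config = transformConfig()) {
  if (is(models, "ClusterModel")) models <- list(models)
  feats <- transformFeatures(dataset, config)
  df <- records(dataset)
  y <- stats::setNames(transformResponse(df$tissue_halflife_h, config),
                       df$protein_id)
  rows <- list()
  for (m in models) {
    ids <- assignment@ids[assignment@labels == m@cluster]
    evalIds <- setdiff(ids, trainIds(m))
    if (length(evalIds) == 0) {
      warning("cluster ", m@cluster, " has an empty evaluation set; omitted")
      next
    }
    pe <- percentageError(predictLinear(feats[evalIds, , drop = FALSE], m),
                          y[evalIds])
    fr <- vapply(thresholds, function(t) mean(pe <= t), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = m@cluster, mode = m@mode, n_eval = length(evalIds),
      as.list(stats::setNames(fr, paste0("pe_", round(100 * thresholds)))),
      stringsAsFactors = FALSE)
  }
  new("EvaluationTable", table = do.call(rbind, rows),
      thresholds = thresholds)
}

#' Repeated-split evaluation summary
#'
#' A single random one-third split is high-variance at typical cluster
#' sizes, so this trains each requested cluster/mode over \code{nRepeats}
#' reseeded splits and reports the mean and standard deviation of the PE
#' fractions.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param profile A \linkS4class{CorrelationProfile} (needed for PCH).
#' @param clusters,modes which cluster/mode combinations to evaluate.
#' @param nRepeats number of reseeded splits (default 10).
#' @param gaCfg A \code{\link{gaConfig}}; repeat r uses seed
#'   \code{gaCfg$seed + r - 1}.
#' @param thresholds PE thresholds as fractions.
#' @param config A \code{\link{transformConfig}}.
#' @return data.frame with mean and sd of each PE fraction per cluster/mode.
#' @export
repeatedEvaluation <- function(dataset, assignment, profile,
                               clusters = c("C1", "C2", "C3"),
                               modes = c("ACH", "PCH"), nRepeats = 10L,
                               gaCfg = gaConfig(),
                               thresholds = c(0.05, 0.10, 0.20, 0.30),
                               config = transformConfig()) {
  cols <- paste0("pe_", round(100 * thresholds))
  out <- list()
  for (cl in clusters) {
    wc <- intercept(fitClusterRegression(dataset, assignment, cl))
    for (md in modes) {
      acc <- matrix(NA_real_, nRepeats, length(thresholds),
                    dimnames = list(NULL, cols))
      for (r in seq_len(nRepeats)) {
        cfg <- gaCfg; cfg$seed <- gaCfg$seed + r - 1L
        m <- trainClusterModel(dataset, assignment, cl, md, profile,
                               interceptWc = wc, gaCfg = cfg,
                               config = config)
        tb <- peTable(evaluatePETable(list(m), assignment, dataset,
                                      thresholds, config))
        acc[r, ] <- as.numeric(tb[1, cols])
      }
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, mode = md, n_repeats = nRepeats,
        as.list(stats::setNames(colMeans(acc), paste0(cols, "_mean"))),
        as.list(stats::setNames(apply(acc, 2, stats::sd),
                                paste0(cols, "_sd"))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
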