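#' @include model.R
NULL

#' Neural-network classifier settings
#'
#' One hidden layer of \code{hiddenUnits} logistic units and a 3-class
#' softmax output trained by cross-entropy (via \code{nnet}). Features are
#' standardized (z-score on the training set) before entering the network.
#'
#' @param hiddenUnits hidden-layer size (default 24).
#' @param maxEpochs maximum training iterations.
#' @param decay L2 weight decay.
#' @param seed RNG seed for the weight initialisation.
#' @return A list of class \code{classifier_spec}.
#' @export
classifierSpec <- function(hiddenUnits = 24L, maxEpochs = 500L,
                           decay = 0.01, seed = 1L) {
  stopifnot(hiddenUnits >= 1, maxEpochs >= 1, decay >= 0)
  structure(list(hiddenUnits = as.integer(hiddenUnits),
                 maxEpochs = as.integer(maxEpochs), decay = decay,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.fitNnet <- function(X, yFac, spec) {
  set.seed(spec$seed)
  nnet::nnet(X, nnet::class.ind(yFac), size = spec$hiddenUnits,
             softmax = TRUE, decay = spec$decay, maxit = spec$maxEpochs,
             trace = FALSE, MaxNWts = 10000L)
}

#' Train the cluster classifier
#'
#' Fits the feedforward network mapping the 7 standardized cellular features
#' of the labeled common proteins to their cluster (C1/C2/C3). The observed
#' cluster frequencies are stored as class priors; by default they reweight
#' the network's class probabilities at classification time. Training
#' accuracy on the labeled proteins is reported in the returned object.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param spec A \code{\link{classifierSpec}}.
#' @param config A \code{\link{transformConfig}}.
#' @param minPerClass minimum labeled proteins required per class.
#' @return A \linkS4class{ClusterClassifier}.
#' @export
#' @examples
#' ds <- generateDataset(liverlikePreset(seed = 3))
#' asg <- assignClusters(ds, fitGlobalRegression(ds))
#' clf <- trainClassifier(ds, asg, classifierSpec(maxEpochs = 100))
#' clf
trainClassifier <- function(dataset, assignment, spec = classifierSpec(),
                            config = transformConfig(), minPerClass = 10L) {
  labs <- clusterLabels(assignment)
  sizes <- table(labs)
  small <- names(sizes)[sizes < minPerClass]
  if (length(small) > 0)
    stop("class(es) with fewer than ", minPerClass, " members: ",
         paste(small, collapse = ", "))
  feats <- transformFeatures(dataset, config)[names(labs), , drop = FALSE]
  center <- colMeans(feats)
  scaleSd <- apply(feats, 2, stats::sd)
  scaleSd[scaleSd == 0] <- 1
  X <- scale(feats, center, scaleSd)
  fit <- .fitNnet(X, labs, spec)
  priors <- as.numeric(sizes) / sum(sizes)
  obj <- new("ClusterClassifier", fit = fit, center = center,
             scaleSd = scaleSd, priors = priors, spec = unclass(spec),
             trainAccuracy = NA_real_)
  pred <- classifyProteins(obj, dataset[names(labs)], usePriors = TRUE)
  obj@trainAccuracy <- mean(pred$label == as.character(labs))
  obj
}

#' Classify proteins into clusters
#'
#' Routes proteins to C1/C2/C3 with the trained network. Probabilities are
#' the softmax outputs; with \code{usePriors} they are multiplied by the
#' observed cluster frequencies and renormalized before the argmax. Both the
#' reweighted and raw probabilities are returned.
#'
#' @param classifier A \linkS4class{ClusterClassifier}.
#' @param dataset A \linkS4class{ProteinDataset} (all 7 features required),
#'   or a pre-transformed feature matrix.
#' @param usePriors reweight by class priors (default TRUE).
#' @param config A \code{\link{transformConfig}}.
#' @return data.frame with protein_id, label, p_C1..p_C3 (used for the
#'   argmax) and raw_p_C1..raw_p_C3 (network output).
#' @export
classifyProteins <- function(classifier, dataset, usePriors = TRUE,
                             config = transformConfig()) {
  feats <- if (is.matrix(dataset)) dataset
           else transformFeatures(dataset, config)
  if (anyNA(feats)) {
    f <- colnames(feats)[which(colSums(is.na(feats)) > 0)[1]]
    stop("missing feature '", f, "' for classification")
  }
  X <- scale(feats, classifier@center, classifier@scaleSd)
  p <- stats::predict(classifier@fit, X)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  colnames(p) <- .clusterLevels
  used <- if (usePriors) {
    q <- sweep(p, 2, classifier@priors, `*`)
    q / rowSums(q)
  } else p
  data.frame(protein_id = rownames(feats),
             label = .clusterLevels[max.col(used, ties.method = "first")],
             stats::setNames(as.data.frame(used), paste0("p_", .clusterLevels)),
             stats::setNames(as.data.frame(p),
                             paste0("raw_p_", .clusterLevels)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Choose the hidden-layer size by cross-validation
#'
#' k-fold cross-validated accuracy for each candidate hidden-unit count;
#' returns the best candidate, breaking ties toward the smallest network.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param candidates hidden-unit counts to try (default includes 24).
#' @param k number of folds.
#' @param spec A \code{\link{classifierSpec}} (hiddenUnits ignored).
#' @param config A \code{\link{transformConfig}}.
#' @return The selected hidden-unit count; per-candidate accuracies are
#'   attached as the \code{"accuracy"} attribute.
#' @export
selectHiddenUnits <- function(dataset, assignment,
                              candidates = c(8L, 16L, 24L, 32L), k = 5L,
                              spec = classifierSpec(),
                              config = transformConfig()) {
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1L)
    return(structure(candidates, accuracy = NA_real_))
  labs <- clusterLabels(assignment)
  feats <- transformFeatures(dataset, config)[names(labs), , drop = FALSE]
  set.seed(spec$seed)
  fold <- sample(rep_len(seq_len(k), length(labs)))
  acc <- vapply(candidates, function(h) {
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      center <- colMeans(feats[tr, , drop = FALSE])
      scaleSd <- apply(feats[tr, , drop = FALSE], 2, stats::sd)
      scaleSd[scaleSd == 0] <- 1
      sp <- spec; sp$hiddenUnits <- h
      fit <- .fitNnet(scale(feats[tr, , drop = FALSE], center, scaleSd),
                      labs[tr], sp)
      p <- stats::predict(fit, scale(feats[!tr, , drop = FALSE],
                                     center, scaleSd))
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      hits <- hits + sum(.clusterLevels[max.col(p, ties.method = "first")] ==
                           as.character(labs[!tr]))
    }
    hits / length(labs)
  }, numeric(1))
  best <- candidates[order(-acc, candidates)][1]
  structure(best, accuracy = stats::setNames(acc, candidates))
}
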