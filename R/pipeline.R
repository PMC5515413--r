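#' @include nn.R
NULL

#' Cluster-calibrated prediction noise
#'
#' Summarises, per cluster, the mean and standard deviation of the common
#' proteins' tissue half-lives; these calibrate the Gaussian noise added to
#' uncommon-protein predictions to emulate the in-tissue variability. The
#' default mode "zero_mean" draws Normal(0, sd_cluster) around the
#' deterministic prediction; mode "paper_literal" draws
#' Normal(mean_cluster, sd_cluster), i.e. the cluster's mean half-life is
#' added on top of the prediction (kept for fidelity audits; it shifts every
#' prediction upward).
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param mode "zero_mean" (default) or "paper_literal".
#' @param seed RNG seed for the noise draws.
#' @return A list of class \code{noise_spec} with the per-cluster
#'   mean/sd table.
#' @export
noiseSpec <- function(dataset, assignment,
                      mode = c("zero_mean", "paper_literal"), seed = 1L) {
  mode <- match.arg(mode)
  df <- records(dataset)
  y <- stats::setNames(df$tissue_halflife_h, df$protein_id)
  labs <- clusterLabels(assignment)
  tab <- do.call(rbind, lapply(.clusterLevels, function(cl) {
    v <- y[names(labs)[labs == cl]]
    data.frame(cluster = cl, mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  if (any(tab$sd < 0)) stop("negative noise sd")  # defensive
  structure(list(table = tab, mode = mode, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Predict tissue half-lives for cell-culture-only proteins
#'
#' Each uncommon protein (no tissue half-life) is routed to a cluster by the
#' neural-network classifier, its tissue half-life predicted with that
#' cluster's trained linear model, and Gaussian noise drawn per the
#' \code{\link{noiseSpec}} added to emulate in-tissue variability. Both the
#' deterministic and the noisy prediction are reported. A non-positive
#' deterministic prediction is flagged and receives no noise.
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param classifier A \linkS4class{ClusterClassifier}.
#' @param models list of \linkS4class{ClusterModel}s covering the clusters
#'   (one mode).
#' @param noise A \code{\link{noiseSpec}}.
#' @param usePriors passed to \code{\link{classifyProteins}}.
#' @param config A \code{\link{transformConfig}}.
#' @return data.frame, one row per uncommon protein: assigned cluster and
#'   probabilities, deterministic prediction, noise draw, noisy prediction,
#'   model mode, and a flag for non-positive deterministic predictions.
#' @export
predictUncommon <- function(dataset, classifier, models, noise,
                            usePriors = TRUE, config = transformConfig()) {
  stopifnot(inherits(noise, "noise_spec"))
  modelOf <- stats::setNames(vector("list", 3), .clusterLevels)
  for (m in models) modelOf[[m@cluster]] <- m
  unc <- dataset[!isCommon(dataset)]
  if (length(unc) == 0L)
    return(data.frame(protein_id = character(), assigned_cluster = character(),
                      p_C1 = numeric(), p_C2 = numeric(), p_C3 = numeric(),
                      predicted_halflife_deterministic = numeric(),
                      noise_draw = numeric(),
                      predicted_halflife_noisy = numeric(),
                      model_mode = character(), flag_nonpositive = logical(),
                      stringsAsFactors = FALSE))
  cls <- classifyProteins(classifier, unc, usePriors = usePriors,
                          config = config)
  feats <- transformFeatures(unc, config)
  det <- numeric(nrow(cls)); mode <- character(nrow(cls))
  for (i in seq_len(nrow(cls))) {
    m <- modelOf[[cls$label[i]]]
    if (is.null(m)) stop("no trained model for cluster ", cls$label[i])
    det[i] <- predictLinear(feats[i, ], m)
    mode[i] <- m@mode
  }
  sdOf <- stats::setNames(noise$table$sd, noise$table$cluster)
  muOf <- if (noise$mode == "paper_literal")
    stats::setNames(noise$table$mean, noise$table$cluster)
  else stats::setNames(rep(0, 3), noise$table$cluster)
  set.seed(noise$seed)
  draw <- stats::rnorm(nrow(cls), muOf[cls$label], sdOf[cls$label])
  bad <- det <= 0
  draw[bad] <- NA_real_
  if (any(bad))
    warning(sum(bad), " uncommon protein(s) with non-positive deterministic",
            " prediction; noise not added")
  data.frame(protein_id = cls$protein_id, assigned_cluster = cls$label,
             cls[paste0("p_", .clusterLevels)],
             predicted_halflife_deterministic = det, noise_draw = draw,
             predicted_halflife_noisy = ifelse(bad, NA_real_, det + draw),
             model_mode = mode, flag_nonpositive = bad,
             stringsAsFactors = FALSE)
}

#' Remove poorly-quantified very-long-lived cell-culture half-lives
#'
#' Cell-culture half-lives above the cutoff (default 200 h) cannot be
#' quantified accurately from short labeling time courses; this splits them
#' off before modeling (strictly greater than the cutoff is removed, the
#' boundary value is kept).
#'
#' @param dataset A \linkS4class{ProteinDataset}.
#' @param cutoff hours (default 200).
#' @return list(kept, removed) of \linkS4class{ProteinDataset}s.
#' @export
#' @examples
#' ds <- generateDataset(liverCohortPreset(seed = 1))
#' sapply(filterLongCellHalflives(ds), length)
filterLongCellHalflives <- function(dataset, cutoff = 200) {
  long <- records(dataset)$cell_halflife_h > cutoff
  list(kept = dataset[!long], removed = dataset[long])
}

#' Pipeline configuration
#'
#' @param input a file path to a canonical TSV/CSV, or a
#'   \code{\link{generatorConfig}} to simulate from (default: the
#'   liver-like preset).
#' @param seed master seed; stage seeds are derived from it.
#' @param bandWidth residual band half-width.
#' @param cutoff cell-half-life cutoff (hours) for exclusion before
#'   modeling; default \code{Inf} (no exclusion). Set to 200 to drop the
#'   poorly-quantified very-long-lived cell-culture measurements, as done
#'   when analysing the shorter-in-tissue subgroup.
#' @param modes feature modes to train ("ACH", "PCH"); the first one is
#'   used for uncommon-protein prediction.
#' @param transform,ga,nn stage configurations.
#' @param noiseMode see \code{\link{noiseSpec}}.
#' @param usePriors prior reweighting during classification.
#' @return A list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(input = NULL, seed = 1L, bandWidth = 0.10,
                           cutoff = Inf, modes = c("ACH", "PCH"),
                           transform = transformConfig(), ga = gaConfig(),
                           nn = classifierSpec(),
                           noiseMode = "zero_mean", usePriors = TRUE) {
  if (is.null(input)) input <- liverlikePreset(seed = seed)
  structure(list(input = input, seed = as.integer(seed),
                 bandWidth = bandWidth, cutoff = cutoff, modes = modes,
                 transform = transform, ga = ga, nn = nn,
                 noiseMode = noiseMode, usePriors = usePriors),
            class = "pipeline_config")
}

.fitAsList <- function(f)
  list(scope = f@scope, slope = f@slope, intercept = f@intercept,
       n = f@n, pearson_r = f@pearsonR, p_value = f@pValue)

.modelAsList <- function(m)
  list(cluster = m@cluster, mode = m@mode,
       weights = as.list(m@weights), intercept_wc = m@interceptWc,
       n_train = length(m@trainIds), seed = m@seed,
       objective_mean = m@objective, objective_sum = m@objectiveSum,
       trace = m@trace)

#' Run the full prediction pipeline
#'
#' Composes the whole method: read or simulate the dataset; exclude
#' cell-culture half-lives above the cutoff; transform features; fit the
#' global tissue~cell regression; partition into residual bands; fit
#' per-cluster regressions; compute the correlation profile and PCH mask;
#' train the per-cluster GA models in the requested modes; tabulate held-out
#' PE fractions; train the neural-network router; predict
#' uncommon-protein half-lives with cluster-calibrated noise; and assemble a
#' reproducible run report. Any stage failure aborts with the stage name.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param outdir optional output directory; when given, the assignment
#'   table, PE table, prediction table, model JSON and run report JSON are
#'   written there (deterministic content for a fixed config).
#' @return Invisibly, a list with all stage results and \code{$report}.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tf <- config$transform

  dataset <- stage("input", {
    if (inherits(config$input, "generator_config"))
      generateDataset(config$input)
    else readProteinDataset(config$input)
  })
  flt <- stage("filter_long_cell", filterLongCellHalflives(dataset,
                                                           config$cutoff))
  ds <- flt$kept

  fit <- stage("global_regression", fitGlobalRegression(ds, tf))
  asg <- stage("assign_clusters",
               assignClusters(ds, fit, bandWidth = config$bandWidth))
  cfits <- stage("cluster_regressions",
                 lapply(stats::setNames(nm = .clusterLevels), function(cl)
                   fitClusterRegression(ds, asg, cl)))
  prof <- stage("correlation_profile", correlationProfile(ds, asg, tf))

  models <- stage("train_models", {
    out <- list()
    for (md in config$modes) for (cl in .clusterLevels) {
      cfg <- config$ga
      cfg$seed <- config$seed + match(cl, .clusterLevels)
      out[[paste(cl, md, sep = "_")]] <- trainClusterModel(
        ds, asg, cl, md, profile = prof,
        interceptWc = intercept(cfits[[cl]]), gaCfg = cfg, config = tf)
    }
    out
  })
  pe <- stage("pe_table", evaluatePETable(models, asg, ds, config = tf))

  nnSpec <- config$nn; nnSpec$seed <- config$seed + 11L
  clf <- stage("train_classifier", trainClassifier(ds, asg, nnSpec, tf))

  primary <- models[paste(.clusterLevels, config$modes[1], sep = "_")]
  nspec <- noiseSpec(ds, asg, mode = config$noiseMode,
                     seed = config$seed + 17L)
  preds <- stage("predict_uncommon",
                 predictUncommon(ds, clf, primary, nspec,
                                 usePriors = config$usePriors, config = tf))

  trainedIds <- sort(unique(unlist(lapply(primary, trainIds))))
  commonIds <- asg@ids
  report <- list(
    package = "halflifeXfer",
    version = as.character(utils::packageVersion("halflifeXfer")),
    seed = config$seed,
    provenance = provenance(dataset),
    counts = list(
      input = length(dataset),
      excluded_long_cell = length(flt$removed),
      common = length(commonIds),
      uncommon_predicted = nrow(preds),
      trained_common = length(trainedIds),
      heldout_common = length(setdiff(commonIds, trainedIds))),
    global_fit = .fitAsList(fit),
    cluster_sizes = as.list(clusterSizes(asg)),
    within_band_r = asg@withinBandR,
    cluster_fits = lapply(cfits, .fitAsList),
    correlations = apply(prof@correlations, 1, as.list, simplify = FALSE),
    pch = apply(pchMask(prof), 1, function(m)
      colnames(pchMask(prof))[m], simplify = FALSE),
    models = lapply(models, .modelAsList),
    pe_table = peTable(pe),
    nn = list(hidden_units = nnSpec$hiddenUnits,
              train_accuracy = clf@trainAccuracy,
              priors = clf@priors),
    noise = list(mode = nspec$mode, table = nspec$table))

  res <- list(dataset = dataset, kept = ds, removed = flt$removed,
              globalFit = fit, assignment = asg, clusterFits = cfits,
              profile = prof, models = models, peTable = pe,
              classifier = clf, noise = nspec, predictions = preds,
              report = report)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, f) utils::write.table(df, file.path(outdir, f),
      sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(data.frame(protein_id = asg@ids, cluster = as.character(asg@labels),
                    deviation = sprintf("%.10g", asg@deviations)),
         "assignments.tsv")
    petab <- peTable(pe)
    pecols <- vapply(petab, is.numeric, logical(1)) &
      grepl("^pe_", names(petab))
    petab[pecols] <- lapply(petab[pecols], function(z) sprintf("%.10g", z))
    wtsv(petab, "pe_table.tsv")
    ptab <- preds
    for (cc in names(ptab)) if (is.numeric(ptab[[cc]]))
      ptab[[cc]] <- sprintf("%.10g", ptab[[cc]])
    wtsv(ptab, "predictions.tsv")
    jsonlite::write_json(lapply(models, .modelAsList),
                         file.path(outdir, "models.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(res)
}
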