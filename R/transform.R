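#' @include AllClasses.R
NULL

#' Feature transform configuration
#'
#' Controls the transform applied to the raw per-protein properties before
#' any modeling. By default every auxiliary property (length, abundance,
#' disorder count, mRNA level, transcription and translation rates) is
#' natural-log transformed and rounded to 4 decimal places, while the two
#' half-lives stay in raw hours so that regression intercepts remain
#' interpretable on the hour scale. Disorder counts of zero are handled by a
#' +1 offset inside the log (log(count + 1)), which maps 0 to 0 and is
#' monotone.
#'
#' @param logFeatures character vector of feature names (see
#'   \code{\link{halflifeFeatures}}) to log-transform.
#' @param roundDecimals decimal places kept after the transform (applied to
#'   transformed features only, never to raw inputs).
#' @param logHalflives if TRUE, also log-transform the cell (and, where used
#'   as a response, tissue) half-life.
#' @param disorderOffset offset added to the disorder count before the log.
#' @return A list of class \code{transform_config}.
#' @export
#' @examples
#' transformConfig()
transformConfig <- function(logFeatures = setdiff(halflifeFeatures(),
                                                  "cell_halflife"),
                            roundDecimals = 4L, logHalflives = FALSE,
                            disorderOffset = 1) {
  stopifnot(all(logFeatures %in% halflifeFeatures()),
            roundDecimals >= 0, disorderOffset >= 0)
  if (logHalflives) logFeatures <- union(logFeatures, "cell_halflife")
  structure(list(logFeatures = logFeatures,
                 roundDecimals = as.integer(roundDecimals),
                 logHalflives = isTRUE(logHalflives),
                 disorderOffset = disorderOffset),
            class = "transform_config")
}

#' Transform per-protein properties into model features
#'
#' Builds the n x 7 feature matrix in canonical order (cell half-life,
#' length, abundance, disorder, mRNA, transcription, translation) from a
#' \linkS4class{ProteinDataset}, applying the configured log transform and
#' rounding. The per-feature transform flags are attached as the
#' \code{"transformFlags"} attribute.
#'
#' @param x A \linkS4class{ProteinDataset} (or canonical data.frame).
#' @param config A \code{\link{transformConfig}}.
#' @return Numeric matrix with one row per protein (rownames = protein ids)
#'   and one column per canonical feature.
#' @export
#' @examples
#' ds <- generateDataset(generatorConfig(nProteins = 5, seed = 1))
#' head(transformFeatures(ds))
transformFeatures <- function(x, config = transformConfig()) {
  df <- if (is(x, "ProteinDataset")) records(x) else as.data.frame(x)
  feats <- halflifeFeatures()
  out <- matrix(NA_real_, nrow(df), length(feats),
                dimnames = list(df$protein_id, feats))
  for (f in feats) {
    v <- as.numeric(df[[.featureColumn[[f]]]])
    if (f %in% config$logFeatures) {
      if (f == "disorder") v <- v + config$disorderOffset
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad) > 0)
        stop("log transform of non-positive value in feature '", f,
             "' (row ", bad[1], ")")
      v <- round(log(v), config$roundDecimals)
    }
    out[, f] <- v
  }
  structure(out, transformFlags = stats::setNames(
    feats %in% config$logFeatures, feats))
}

#' Transform the tissue half-life response per the configuration
#'
#' Identity on raw hours unless \code{logHalflives} is set.
#'
#' @param y numeric tissue half-lives (hours).
#' @param config A \code{\link{transformConfig}}.
#' @return Numeric vector on the modeling scale.
#' @keywords internal
transformResponse <- function(y, config = transformConfig()) {
  if (config$logHalflives) {
    if (any(!is.na(y) & y <= 0)) stop("log transform of non-positive half-life")
    round(log(y), config$roundDecimals)
  } else y
}
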