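#' @include transform.R
NULL

#' Read a per-protein half-life table
#'
#' Reads a TSV (default) or CSV file with a header row into a
#' \linkS4class{ProteinDataset}. Columns are matched by the canonical names
#' (\code{\link{canonicalColumns}}) unless a \code{columnMap} renames them.
#' A missing \code{tissue_halflife_h} value marks the protein as uncommon
#' (observed only in cell culture). Rows violating the positivity invariants
#' or with unparseable numbers are rejected with a row-level report (stored
#' in the dataset metadata and emitted as a warning); the remaining rows are
#' loaded.
#'
#' @param path file to read.
#' @param format "tsv" or "csv".
#' @param columnMap optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(cell_halflife_h = "t50.cell")}.
#' @param provenance provenance label recorded in the dataset (defaults to
#'   the file name).
#' @return A \linkS4class{ProteinDataset}. Rejected rows (if any) are in
#'   \code{x@metadata$rejected_rows}.
#' @export
readProteinDataset <- function(path, format = c("tsv", "csv"),
                               columnMap = NULL, provenance = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (format == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  wanted <- canonicalColumns()
  src <- stats::setNames(wanted, wanted)
  if (!is.null(columnMap)) src[names(columnMap)] <- columnMap
  missing <- wanted[!src[wanted] %in% names(raw)]
  if (length(missing) > 0)
    stop("input lacks required column(s): ", paste(missing, collapse = ", "))
  df <- stats::setNames(raw[, src[wanted], drop = FALSE], wanted)

  numCols <- setdiff(wanted, "protein_id")
  reasons <- character(nrow(df))
  for (col in numCols) {
    v <- df[[col]]
    isBlank <- is.na(v) | (is.character(v) & trimws(as.character(v)) == "")
    num <- suppressWarnings(as.numeric(v))
    badParse <- !isBlank & is.na(num)
    if (col == "tissue_halflife_h") {
      bad <- badParse | (!is.na(num) & num <= 0)
    } else if (col == "disorder_count") {
      bad <- isBlank | badParse | (!is.na(num) & num < 0)
    } else {
      bad <- isBlank | badParse | (!is.na(num) & num <= 0)
    }
    reasons[bad] <- ifelse(reasons[bad] == "", paste("invalid", col),
                           reasons[bad])
    df[[col]] <- num
  }
  df$protein_id <- as.character(df$protein_id)
  reasons[is.na(df$protein_id) | df$protein_id == ""] <- "missing protein_id"

  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " row(s) rejected; see metadata$rejected_rows ",
            "(first: row ", rejected$row[1], ", ", rejected$reason[1], ")")
  ProteinDataset(df[keep, , drop = FALSE], provenance = provenance,
                 metadata = list(rejected_rows = rejected))
}

#' Write a ProteinDataset to a canonical TSV/CSV
#'
#' Numeric fields are written with enough significant digits that a
#' read/write round trip reproduces them exactly; missing tissue half-lives
#' (uncommon proteins) are written as empty fields.
#'
#' @param x A \linkS4class{ProteinDataset}.
#' @param path output file path.
#' @param format "tsv" or "csv".
#' @return The path, invisibly.
#' @export
writeProteinDataset <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is(x, "ProteinDataset"))
  df <- records(x)
  num <- setdiff(canonicalColumns(), "protein_id")
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", formatC(v, digits = 15, format = "g")))
  utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
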