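## Tab-delimited interchange: expression matrices (first column feature id,
## header row of sample ids) and sample sheets.

#' Read and write tab-delimited expression matrices
#'
#' The on-disk layout is a header row of sample identifiers and a first
#' column of feature identifiers (column name \code{feature_id}).
#'
#' @param m numeric feature-by-sample matrix with dimnames.
#' @param path file path.
#' @return \code{readExpressionTsv} returns the numeric matrix;
#'   \code{writeExpressionTsv} invisibly returns \code{path}.
#' @export
writeExpressionTsv <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read and write sample sheets
#'
#' Tab-delimited with columns \code{sample_id}, \code{tissue} (T/P),
#' \code{dose} (sham/L/M/H), \code{animal_id}, \code{is_replicate}.
#'
#' @param sheet sample-sheet data.frame.
#' @param path file path.
#' @return \code{readSampleSheet} returns the data.frame;
#'   \code{writeSampleSheet} invisibly returns \code{path}.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue", "dose") %in% names(df)))
    stop("sample sheet needs at least sample_id, tissue, dose columns")
  if ("is_replicate" %in% names(df))
    df$is_replicate <- as.logical(df$is_replicate)
  df
}

#' Write a planted truth table
#'
#' @param truth a truth table as returned by \code{\link{truthTable}}.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
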