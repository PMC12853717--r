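#' Read and write left-censored data as CSV
#'
#' The on-disk convention is one numeric column per variable plus a logical
#' companion column `"<var>_censored"` for the left-censored variable; a
#' header row is required. The LLOQ is not inferred from the file — it is
#' always supplied by the caller (or a config). When the flag column is
#' absent, `read_bloq_csv()` derives it by the sentinel convention
#' `value <= lloq`.
#'
#' @param path CSV file path.
#' @param bloq_var Name of the left-censored column.
#' @param lloq Positive threshold.
#' @param data Data frame to write; censored slots of `bloq_var` should
#'   hold the sentinel `lloq` (or, for a completed dataset, the imputed
#'   values, in which case pass `imputed_by` to record provenance).
#' @param imputed_by Optional method tag written as a constant provenance
#'   column `"imputed_by"`.
#'
#' @return `read_bloq_csv()`: a data frame with `bloq_var`, the logical
#'   `"<bloq_var>_censored"` column, and attribute `"lloq"`.
#'   `write_bloq_csv()`: the path, invisibly.
#' @name bloq_csv
NULL

#' @rdname bloq_csv
#' @export
read_bloq_csv <- function(path, bloq_var, lloq) {
  d <- utils::read.csv(path, header = TRUE)
  if (!bloq_var %in% names(d)) {
    stop("column '", bloq_var, "' not found in ", path)
  }
  flag_col <- paste0(bloq_var, "_censored")
  if (flag_col %in% names(d)) {
    d[[flag_col]] <- as.logical(d[[flag_col]])
  } else {
    d[[flag_col]] <- d[[bloq_var]] <= lloq
  }
  d[[bloq_var]][d[[flag_col]]] <- lloq
  attr(d, "lloq") <- lloq
  d
}

#' @rdname bloq_csv
#' @export
write_bloq_csv <- function(data, path, imputed_by = NULL) {
  if (!is.null(imputed_by)) data$imputed_by <- imputed_by
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
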