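# Delimited-text IO with provenance headers.

#' Write a result table as tab-separated text with a header comment
#'
#' @param x Data frame.
#' @param path Output file.
#' @param header Comment line(s) (already prefixed with `#`), e.g. carrying
#'   the configuration hash and seed.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Input file.
#' @return A tibble; header comment lines are skipped.
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Write a capture time series as a delimited table
#'
#' Columns: `time_min`, `frac_occupancy`, `captured_density_per_um2`,
#' `bound`, `free`, `escaped`, `residual`.
#'
#' @param series A capture time series.
#' @param path Output file.
#' @param header Optional comment line(s).
#' @return Invisibly, `path`.
#' @export
write_capture_series <- function(series, path, header = NULL) {
  write_result_table(as.data.frame(series), path, header)
}
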