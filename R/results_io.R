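#' Write a results table to TSV with stable column order
#'
#' All pipeline stages persist their tabular outputs through this writer:
#' tab-separated, header always present (an empty record set yields a
#' header-only file), numeric columns at fixed precision so files are
#' byte-reproducible.
#'
#' @param records data.frame of records sharing one schema.
#' @param path Output path.
#' @param digits Significant digits used for floating-point columns.
#' @return The path, invisibly.
#' @export
write_results_table <- function(records, path, digits = 6) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(out[[j]], digits = digits, format = "g"))
    }
  }
  write_tsv_file(out, path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) {
    ps_abort(sprintf("results file not found: %s", path), "io_error")
  }
  utils::read.delim(path, check.names = FALSE)
}
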