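#' Write a result table as TSV
#'
#' Tab-delimited UTF-8 with a header row and deterministic column order
#' (the order of the supplied data.frame).  P-value columns (names equal to
#' `p`, starting with `p_`, or ending in `_p`) are rendered in scientific
#' notation with enough digits to round-trip to 1e-12 relative.
#'
#' @param rows data.frame of result records; may have zero rows.
#' @param path output path.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  is_p <- grepl("^p$|^p_|_p$", names(rows)) &
    vapply(rows, is.numeric, logical(1L))
  for (j in which(is_p)) rows[[j]] <- sprintf("%.12e", rows[[j]])
  ok <- tryCatch({
    data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write results table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#' @param path file path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(data.table::fread(path, sep = "\t"))
}
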