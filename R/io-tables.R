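# Tabular/JSON output helpers: UTF-8 TSV with a header row and '.'
# decimal separator, and JSON summaries via jsonlite.

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a JSON summary
#'
#' @param x list to serialise.
#' @param path output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
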