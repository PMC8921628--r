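#' Table input/output
#'
#' The canonical table dialect is tab-separated values with a header row,
#' UTF-8, no quoting of HGVS strings. Comma-separated files are accepted on
#' read (delimiter sniffed from the header line).
#'
#' @name table_io
NULL

#' @rdname table_io
#' @param df A data.frame.
#' @param path File path.
#' @return `path` invisibly (write) or a data.frame (read).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, seeds and settings of a run as JSON so any artifact can
#' be regenerated.
#'
#' @param path Output path.
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package_version <- as.character(utils::packageVersion("missprof"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
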