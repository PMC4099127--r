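# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing validation failures in the package raise conditions whose
#' class carries a stable machine-readable name (`lnchcc_<name>`), so callers
#' and tests can distinguish failure modes without parsing messages.
#'
#' @param msg message text.
#' @param class short error class suffix, e.g. "duplicate_ids".
#' @noRd
abort_lnchcc <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("lnchcc_", class), "lnchcc_error")))
}

#' Hash a configuration object
#'
#' Stable MD5 of the deparsed object; used to stamp output files so that
#' results produced under different configurations are distinguishable.
#'
#' @param x any R object.
#' @return a 32-character hexadecimal string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

# Comment header stamped at the top of TSV/CSV outputs.
output_header <- function(hash = NULL) {
  ver <- as.character(utils::packageVersion("lnchcc"))
  h <- if (is.null(hash)) "unspecified" else hash
  c(sprintf("# lnchcc %s", ver), sprintf("# config_hash: %s", h))
}

#' Stamped tabular output and its reader
#'
#' `write_table_with_header()` writes a data frame with a two-line `#`
#' comment header carrying the package version and a configuration hash, so
#' results produced under different configurations are distinguishable.
#' `read_table_skip_comments()` reads such files (and any table whose
#' comment lines start with `#`).
#'
#' @param df data frame to write.
#' @param path file path.
#' @param hash configuration hash (see [config_hash()]).
#' @param sep field separator.
#' @param ... further arguments to [utils::read.table()].
#' @return `write_table_with_header()` returns `path` invisibly;
#'   `read_table_skip_comments()` returns a data frame.
#' @export
write_table_with_header <- function(df, path, hash = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(hash), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_with_header
#' @export
read_table_skip_comments <- function(path, sep = "\t", ...) {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
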