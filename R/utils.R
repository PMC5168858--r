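#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames aggregate quantile
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# case-insensitive fixed/regex containment on a character vector
ci_detect <- function(x, patterns) {
  x <- tolower(x)
  hit <- rep(FALSE, length(x))
  for (p in patterns) hit <- hit | grepl(p, x, fixed = TRUE)
  hit
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# collapse an integer vector to "a,b,c"; empty -> ""
int_csv <- function(x) paste(x, collapse = ",")

csv_int <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Write a data frame as a TSV report
#'
#' Plain tab-separated output, no quoting, no row names; the on-disk format
#' used for every intermediate and report table in the pipeline.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
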