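#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cpcnet <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cpcnet_error")))
}

#' Write a data frame as TSV
#'
#' Plain TSV writer used for every tabular output of the pipeline: tab
#' separated, header row, no quoting, no row names, `NA` written as an
#' empty field so downstream readers can distinguish "absent" from
#' "measured zero".
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "", fill = TRUE, ...)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Split a ";"-separated field into a character vector (empty -> character(0)).
split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}
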