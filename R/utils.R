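#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the pipeline driver) can tell a malformed
# file from an invalid value.
stop_format <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("gsl_format_error", "error", "condition")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("gsl_validation_error", "error", "condition")))
}

#' Round half away from zero
#'
#' Commercial rounding used for all published-precision reporting (percentages
#' to 1 decimal, contents to 3). Base [round()] rounds half to even, which
#' disagrees with printed tables at exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("%s: missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
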