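# Internal helpers shared across modules.

DAYS_PER_YEAR <- 365.25
SIX_MONTHS_DAYS <- 182.625

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

as_date_col <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (is.numeric(x)) return(as.Date(x, origin = "1970-01-01"))
  as.Date(as.character(x))
}

# sample skewness m3 / m2^(3/2); NA when undefined (n < 3 or zero variance)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Read a tab-separated table
#'
#' Thin wrapper over [data.table::fread()] fixing the separator and string
#' handling used by all package file formats.
#'
#' @param path file path.
#' @param ... passed to `fread`.
#' @return a `data.table`.
#' @export
read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                    colClasses = NULL, data.table = TRUE, ...)
}

#' Write a tab-separated table
#'
#' @param x table to write.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Path to a packaged data file
#'
#' @param ... path components under `inst/extdata`.
#' @return absolute path.
#' @export
ehrpheno_extdata <- function(...) {
  system.file("extdata", ..., package = "ehrpheno", mustWork = TRUE)
}
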