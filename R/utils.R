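#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort frequency tables are
#' conventionally reported with half-up rounding (14/49 -> 28.6%).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_columns <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required field(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
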