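#' @keywords internal
"_PACKAGE"

#' Geometric mean
#'
#' @param x numeric vector, all values > 0.
#' @return the geometric mean of `x`.
#' @keywords internal
geom_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## stop() with sprintf formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x > 0

#' Format doubles so that read.csv/read.delim recovers them bit-exactly
#' @keywords internal
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ## integers print without exponent for readability
  ival <- !is.na(x) & x == round(x) & abs(x) < 2^53
  out[ival] <- sprintf("%.0f", x[ival])
  out
}

## reverse complement for plain character genomes (ACGTN)
revcomp <- function(seq) {
  chartr("ACGTacgtN", "TGCAtgcaN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
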