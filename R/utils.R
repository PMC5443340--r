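#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used by the printed tables this
#' package reproduces. Base R's `round()` rounds half to even, which turns
#' e.g. a loss of 19.05% into 19.0 rather than the conventionally printed
#' 19.1.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` places, ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # nudge guards against binary representations just below .5 (e.g. 43.4999...)
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# single probability check used by constructors
assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single non-negative%s number", name,
                 if (positive) ", strictly positive" else ""), call. = FALSE)
  }
  invisible(x)
}

# type-7 quantiles (linear interpolation between order statistics), the
# package-wide percentile convention
percentile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}
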