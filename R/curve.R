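#' Sampled spectral curve
#'
#' Constructs a `spectral_curve`, the package's basic data structure: a curve
#' sampled at `N >= 3` strictly increasing frequencies, each carrying one
#' finite value (typically absorption or extinction coefficient from a
#' THz-TDS measurement, but any units work -- the method is scale-free).
#'
#' @param frequency Numeric vector of sampling frequencies, strictly
#'   increasing, length at least 3. Arbitrary units.
#' @param value Numeric vector of the same length; the curve's values
#'   (absorption, extinction, ...). Must be finite.
#'
#' @return An object of class `spectral_curve`: a list with elements
#'   `frequency` and `value`.
#'
#' @examples
#' crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
#' print(crv)
#' @export
spectral_curve <- function(frequency, value) {
  frequency <- as.numeric(frequency)
  value <- as.numeric(value)
  if (length(frequency) != length(value)) {
    nuc_abort("`frequency` and `value` must have the same length (got %d and %d)",
              length(frequency), length(value))
  }
  n <- length(frequency)
  if (n < 3) {
    nuc_abort("a spectral curve needs at least 3 samples (got %d)", n)
  }
  if (anyNA(frequency) || any(!is.finite(frequency))) {
    nuc_abort("frequencies must be finite (offending row %d)",
              which(!is.finite(frequency))[1L])
  }
  if (anyNA(value) || any(!is.finite(value))) {
    nuc_abort("values must be finite (offending row %d)",
              which(!is.finite(value))[1L])
  }
  d <- diff(frequency)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    if (d[bad - 1L] == 0) {
      nuc_abort("duplicate frequency at row %d", bad)
    }
    nuc_abort("frequencies must be strictly increasing (violated at row %d)", bad)
  }
  structure(list(frequency = frequency, value = value), class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  n <- length(x$frequency)
  cat(sprintf("<spectral_curve: %d samples, frequency [%g, %g], value range %g>\n",
              n, x$frequency[1L], x$frequency[n], diff(range(x$value))))
  invisible(x)
}

#' @export
as.data.frame.spectral_curve <- function(x, ...) {
  data.frame(frequency = x$frequency, value = x$value)
}

#' @export
length.spectral_curve <- function(x) length(x$frequency)

#' Value range of a spectral curve
#'
#' @param curve A [spectral_curve()].
#' @return `max(value) - min(value)`, a non-negative scalar.
#' @export
value_range <- function(curve) {
  stopifnot(inherits(curve, "spectral_curve"))
  diff(range(curve$value))
}

# Structured validation error; the CLI maps this condition class to exit code 2.
nuc_abort <- function(fmt, ..., class = "nuc_validation_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "nuc_error")))
}
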