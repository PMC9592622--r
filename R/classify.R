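#' Classify the interior points of a curve
#'
#' Labels every sample of a curve as one of `local_max`, `local_min`, `bump`,
#' `pit` or `plain`. The four non-plain classes are the candidate convex-hull
#' vertices the fast band search works with:
#'
#' * `local_max` -- strictly above both neighbours;
#' * `local_min` -- strictly below both neighbours;
#' * `bump` -- interior point of a strictly monotone run whose consecutive
#'   increments strictly decrease (locally concave);
#' * `pit` -- interior point of a strictly monotone run whose consecutive
#'   increments strictly increase (locally convex).
#'
#' The classes are mutually exclusive. Endpoints are always `plain`, as are
#' points adjacent to an equal-valued neighbour (plateaus): every comparison
#' is strict, so ties fall through to `plain` with no special casing.
#'
#' @param curve A [spectral_curve()].
#' @param tol Absolute tolerance for value comparisons: `a > b` is taken as
#'   `a - b > tol`. The default 0 reproduces exact strict comparison;
#'   a small positive value lets noisy plateaus count as equal.
#' @return A character vector of length `N` with entries in
#'   `c("plain", "local_max", "local_min", "bump", "pit")`.
#'
#' @examples
#' classify_points(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' @export
classify_points <- function(curve, tol = 0) {
  stopifnot(inherits(curve, "spectral_curve"))
  v <- curve$value
  n <- length(v)
  gt <- function(a, b) (a - b) > tol

  labels <- rep("plain", n)
  i <- 2:(n - 1L)
  up_l <- gt(v[i], v[i - 1L])        # strictly rising into i
  dn_l <- gt(v[i - 1L], v[i])        # strictly falling into i
  up_r <- gt(v[i + 1L], v[i])        # strictly rising out of i
  dn_r <- gt(v[i], v[i + 1L])        # strictly falling out of i

  loc_max <- up_l & dn_r
  loc_min <- dn_l & up_r
  mono <- (up_l & up_r) | (dn_l & dn_r)
  dl <- v[i] - v[i - 1L]
  dr <- v[i + 1L] - v[i]
  bump <- mono & gt(dl, dr)
  pit <- mono & gt(dr, dl)

  labels[i][loc_max] <- "local_max"
  labels[i][loc_min] <- "local_min"
  labels[i][bump] <- "bump"
  labels[i][pit] <- "pit"
  labels
}

#' Index sets of a curve's extreme and curvature points
#'
#' Collects the 1-based index sets the band search is built on: `A` and `B`
#' hold every index attaining the global maximum and minimum respectively;
#' `A1`/`B1` the local maxima/minima; `A2`/`B2` the bump/pit points (see
#' [classify_points()]).
#'
#' @param curve A [spectral_curve()].
#' @param labels Optional labels from [classify_points()] on the same curve;
#'   recomputed if missing.
#' @inheritParams classify_points
#' @return An object of class `nuc_index_sets`: a list with integer-vector
#'   elements `A`, `A1`, `A2`, `B`, `B1`, `B2`.
#'
#' @examples
#' index_sets(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' @export
index_sets <- function(curve, labels = NULL, tol = 0) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (is.null(labels)) labels <- classify_points(curve, tol = tol)
  v <- curve$value
  structure(list(
    A  = which(v >= max(v) - tol),
    A1 = which(labels == "local_max"),
    A2 = which(labels == "bump"),
    B  = which(v <= min(v) + tol),
    B1 = which(labels == "local_min"),
    B2 = which(labels == "pit")
  ), class = "nuc_index_sets")
}

#' @export
print.nuc_index_sets <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-3s: {%s}\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Extreme-index anchors of a curve
#'
#' The four rotation anchors of the band search: `a1`/`a2` are the leftmost
#' and rightmost indices attaining the global maximum, `b1`/`b2` the leftmost
#' and rightmost indices attaining the global minimum. `a1 == a2` exactly
#' when the global maximum is unique (likewise for the minimum).
#'
#' @param sets Index sets from [index_sets()].
#' @return An object of class `nuc_anchors`: a list with integer scalars
#'   `a1`, `a2`, `b1`, `b2`.
#'
#' @examples
#' curve_anchors(index_sets(spectral_curve(0:4, c(0, 3, 1, 4, 2))))
#' @export
curve_anchors <- function(sets) {
  stopifnot(inherits(sets, "nuc_index_sets"))
  structure(list(a1 = min(sets$A), a2 = max(sets$A),
                 b1 = min(sets$B), b2 = max(sets$B)),
            class = "nuc_anchors")
}

#' @export
print.nuc_anchors <- function(x, ...) {
  cat(sprintf("<anchors a1=%d a2=%d b1=%d b2=%d, processable=%s>\n",
              x$a1, x$a2, x$b1, x$b2, is_processable(x)))
  invisible(x)
}

#' Adaptation test: can a curve be narrowed by an anchored shear?
#'
#' A curve admits a range-reducing shear exactly when both global-maximum
#' indices lie strictly on one side of both global-minimum indices, i.e.
#' `(a1 - b2) * (b1 - a2) < 0`. When the extremes interleave no anchored
#' rotation can tighten the band and the iteration stops. Flat curves
#' (every point both a maximum and a minimum) always fail the test.
#'
#' @param x A `nuc_anchors` object, or a [spectral_curve()] (anchors are then
#'   computed first).
#' @param ... Passed on to methods; for curves, `tol` is forwarded to
#'   [index_sets()].
#' @return `TRUE` or `FALSE`.
#'
#' @examples
#' is_processable(spectral_curve(0:4, c(0, 3, 1, 4, 2)))   # TRUE
#' is_processable(spectral_curve(0:2, c(1, 0, 1)))         # FALSE
#' @export
is_processable <- function(x, ...) UseMethod("is_processable")

#' @rdname is_processable
#' @export
is_processable.nuc_anchors <- function(x, ...) {
  (x$a1 - x$b2) * (x$b1 - x$a2) < 0
}

#' @rdname is_processable
#' @param tol Value-comparison tolerance, see [classify_points()].
#' @export
is_processable.spectral_curve <- function(x, tol = 0, ...) {
  is_processable(curve_anchors(index_sets(x, tol = tol)))
}
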