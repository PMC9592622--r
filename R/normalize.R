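#' Normalize a curve into the unit square
#'
#' Translates and zooms a curve so that it is inlaid into the unit square:
#' `x(1) = 0`, `x(N) = 1` and the values span exactly `[0, 1]`, with
#' `y = 1` at every global-maximum index and `y = 0` at every global-minimum
#' index. Point classes ([classify_points()]) are invariant under this map
#' because it is strictly monotone in both coordinates.
#'
#' The affine parameters are kept on the object so the transform can be
#' inverted: `frequency = x / x_scale - x_offset` and
#' `value = y / y_scale - y_offset`.
#'
#' @param curve A [spectral_curve()] whose values are not all equal.
#' @return An object of class `nuc_normalized`: a list with numeric vectors
#'   `x`, `y` and scalars `x_offset` (`-f_1`), `y_offset` (`-min(value)`),
#'   `x_scale` (`1 / (f_N - f_1)`), `y_scale` (`1 / (max - min)`).
#'
#' @examples
#' normalize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "spectral_curve"))
  f <- curve$frequency
  v <- curve$value
  n <- length(f)
  vmin <- min(v)
  vmax <- max(v)
  if (vmax == vmin) {
    nuc_abort("cannot normalize a flat curve (max == min)",
              class = "nuc_degenerate_error")
  }
  xs <- 1 / (f[n] - f[1L])
  ys <- 1 / (vmax - vmin)
  structure(list(
    x = (f - f[1L]) * xs,
    y = (v - vmin) * ys,
    x_offset = -f[1L], y_offset = -vmin,
    x_scale = xs, y_scale = ys
  ), class = "nuc_normalized")
}

#' @export
print.nuc_normalized <- function(x, ...) {
  cat(sprintf("<normalized curve: %d points in the unit square>\n", length(x$x)))
  invisible(x)
}

#' Invert a unit-square normalization
#'
#' @param norm A `nuc_normalized` object.
#' @return A [spectral_curve()] reproducing the original samples (up to
#'   floating rounding).
#' @export
denormalize_curve <- function(norm) {
  stopifnot(inherits(norm, "nuc_normalized"))
  spectral_curve(norm$x / norm$x_scale - norm$x_offset,
                 norm$y / norm$y_scale - norm$y_offset)
}

#' Slope between two normalized points
#'
#' The slope of the segment joining points `i` and `j` of a normalized
#' curve, with the degenerate self-slope defined as 0 so that a candidate
#' set that has collapsed to the anchor itself yields a zero rotation.
#' Because the `x` coordinates are strictly increasing the slope is always
#' finite. Vectorized over `i`.
#'
#' @param norm A `nuc_normalized` object.
#' @param i,j 1-based point indices (`i` may be a vector).
#' @return Numeric slope(s).
#'
#' @examples
#' nrm <- normalize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' curve_slope(nrm, 2, 4)   # 0.5
#' curve_slope(nrm, 4, 4)   # 0
#' @export
curve_slope <- function(norm, i, j) {
  stopifnot(inherits(norm, "nuc_normalized"))
  s <- (norm$y[i] - norm$y[j]) / (norm$x[i] - norm$x[j])
  s[i == j] <- 0
  s
}

#' Candidate convex-hull points for the four anchored rotations
#'
#' Restricts the support-slope search to the only points that can carry a
#' convex-hull edge on each side of each anchor: the relevant endpoint plus
#' the local maxima and bumps (top line) or local minima and pits (bottom
#' line) strictly outside the anchor. Interior points of straight or
#' convex-the-wrong-way runs can never be support contacts and are filtered
#' out, which is what makes the search fast.
#'
#' @param sets Index sets from [index_sets()].
#' @param anchors Anchors from [curve_anchors()].
#' @param n Number of samples in the curve.
#' @return An object of class `nuc_candidates`: a list with integer-vector
#'   elements `A3` (left of `a1`, plus index 1), `A4` (right of `a2`, plus
#'   `n`), `B3` (left of `b1`, plus 1) and `B4` (right of `b2`, plus `n`).
#'
#' @examples
#' crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
#' sets <- index_sets(crv)
#' candidate_sets(sets, curve_anchors(sets), length(crv))
#' @export
candidate_sets <- function(sets, anchors, n) {
  stopifnot(inherits(sets, "nuc_index_sets"), inherits(anchors, "nuc_anchors"))
  top <- sort(union(sets$A1, sets$A2))
  bot <- sort(union(sets$B1, sets$B2))
  structure(list(
    A3 = unique(c(1L, top[top < anchors$a1])),
    A4 = sort(unique(c(n, top[top > anchors$a2]))),
    B3 = unique(c(1L, bot[bot < anchors$b1])),
    B4 = sort(unique(c(n, bot[bot > anchors$b2])))
  ), class = "nuc_candidates")
}

#' @export
print.nuc_candidates <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-3s: {%s}\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
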