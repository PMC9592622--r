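#' Convex hull of a normalized curve by Andrew's monotone chain
#'
#' Brute-force reference geometry: builds the full convex hull of the
#' normalized sample points. The points are already sorted by strictly
#' increasing `x`, so the monotone chain reduces to one left-to-right pass
#' for the lower chain and one right-to-left pass for the upper chain.
#' Collinear boundary points are excluded from the vertex list (strict
#' turns only, cross-product tolerance `tol`). This routine exists for
#' validating the fast anchored-rotation search and is never on the fast
#' path.
#'
#' @param norm A [normalize_curve()] result.
#' @param tol Cross-product collinearity tolerance (default `1e-12`).
#' @return An object of class `nuc_hull`: a list with `vertices` (indices
#'   in counterclockwise order starting from the leftmost point), `lower`
#'   and `upper` (chain indices, each left to right), and `degenerate`
#'   (`TRUE` when all points are collinear, in which case `vertices` holds
#'   just the two endpoints and `line_slope` the common slope).
#'
#' @examples
#' nrm <- normalize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' convex_hull_chain(nrm)$vertices   # 1 5 4 2
#' @export
convex_hull_chain <- function(norm, tol = 1e-12) {
  stopifnot(inherits(norm, "nuc_normalized"))
  x <- norm$x
  y <- norm$y
  n <- length(x)
  cross <- function(o, a, b) {
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  }
  chain <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(h[length(h) - 1L], h[length(h)], i) <= tol) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- chain(seq_len(n))            # left to right, below the curve
  upper_rl <- chain(rev(seq_len(n)))    # right to left, above the curve
  degenerate <- length(lower) == 2 && length(upper_rl) == 2
  vertices <- c(lower[-length(lower)], upper_rl[-length(upper_rl)])
  structure(list(
    vertices = vertices,
    lower = lower,
    upper = rev(upper_rl),
    degenerate = degenerate,
    line_slope = if (degenerate) curve_slope(norm, n, 1L) else NULL
  ), class = "nuc_hull")
}

#' @export
print.nuc_hull <- function(x, ...) {
  cat(sprintf("<convex hull: %d vertices%s: %s>\n", length(x$vertices),
              if (x$degenerate) " (degenerate, collinear)" else "",
              paste(x$vertices, collapse = " ")))
  invisible(x)
}

#' Exhaustive support slope through an extreme anchor
#'
#' Reference computation for the critical rotations: scans every index
#' strictly on the given side of the anchor (no candidate filtering) and
#' returns the signed slope of largest magnitude for which the line through
#' the anchor is still a support line of the curve. For an anchor at the
#' global maximum (`line = "top"`) the left-side support slope is the
#' minimum of the point-to-anchor slopes and the right-side one the
#' maximum; for a global-minimum anchor (`line = "bottom"`) the roles swap.
#' An empty side yields 0 (no rotation possible), matching the degenerate
#' self-slope convention of [curve_slope()].
#'
#' @param norm A [normalize_curve()] result.
#' @param anchor Index of the anchor, which must attain `y = 1` for
#'   `line = "top"` or `y = 0` for `line = "bottom"`.
#' @param side `"left"` or `"right"`: which side of the anchor to scan.
#' @param line `"top"` or `"bottom"`: which support line the anchor holds.
#' @return The signed support slope (a scalar).
#'
#' @examples
#' nrm <- normalize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' support_slope_exhaustive(nrm, 4, "left", "top")   # 0.5
#' @export
support_slope_exhaustive <- function(norm, anchor,
                                     side = c("left", "right"),
                                     line = c("top", "bottom")) {
  stopifnot(inherits(norm, "nuc_normalized"))
  side <- match.arg(side)
  line <- match.arg(line)
  n <- length(norm$x)
  idx <- if (side == "left") seq_len(anchor - 1L) else
    if (anchor < n) (anchor + 1L):n else integer(0)
  if (length(idx) == 0) return(0)
  s <- curve_slope(norm, idx, anchor)
  # top/left and bottom/right bind from above (take the min slope);
  # top/right and bottom/left bind from below (take the max slope)
  if (xor(side == "left", line == "bottom")) min(s) else max(s)
}

#' Global minimum vertical band of a normalized curve
#'
#' Reference optimum for the whole pretreatment: the narrowest pair of
#' parallel lines of any slope confining all points, measured as vertical
#' (y-axis) extent. The width `w(m) = max(y - m x) - min(y - m x)` is a
#' piecewise-linear convex function of the slope `m`, so its minimum is
#' attained at a breakpoint -- one of the pairwise point slopes (or 0).
#' This brute force evaluates them all; it is `O(N^3)` by design and only
#' used for testing.
#'
#' No single anchored-rotation pass can beat this width, and neither can a
#' full iterated run: every pass subtracts a line, so the final range ratio
#' of [nuc()] is bounded below by this width.
#'
#' @param norm A [normalize_curve()] result.
#' @param tol Containment/contact tolerance (default `1e-12`).
#' @return An object of class `nuc_band`: a list with `slope` (`m`),
#'   `width` (`w`), `contacts_top` and `contacts_bottom` (indices touching
#'   the two lines), and `degenerate` (`TRUE` for collinear input, width
#'   0 at the common slope).
#'
#' @examples
#' nrm <- normalize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)))
#' min_vertical_band(nrm)[c("slope", "width")]   # m = 0.5, w = 0.625
#' @export
min_vertical_band <- function(norm, tol = 1e-12) {
  stopifnot(inherits(norm, "nuc_normalized"))
  x <- norm$x
  y <- norm$y
  n <- length(x)
  pairs <- utils::combn(n, 2)
  ms <- unique(c(0, (y[pairs[1L, ]] - y[pairs[2L, ]]) /
                    (x[pairs[1L, ]] - x[pairs[2L, ]])))
  resid <- matrix(y, n, length(ms)) - outer(x, ms)   # y - m*x, one column per m
  w <- apply(resid, 2L, max) - apply(resid, 2L, min)
  best <- which.min(w)
  m <- ms[best]
  r <- y - m * x
  structure(list(
    slope = m,
    width = w[best],
    contacts_top = which(r >= max(r) - tol),
    contacts_bottom = which(r <= min(r) + tol),
    degenerate = w[best] <= tol
  ), class = "nuc_band")
}
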