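#' The four anchored critical rotations of a normalized curve
#'
#' For each of the four rotation cases, finds the critical point at which a
#' line rotating about the case's fixed anchor first touches the curve, i.e.
#' becomes a support line of the convex hull:
#'
#' * case 1 -- top line anchored at `a1` (leftmost global max), critical
#'   point searched to its left among `A3`;
#' * case 2 -- top line anchored at `a2` (rightmost global max), searched to
#'   its right among `A4`;
#' * case 3 -- bottom line anchored at `b1` (leftmost global min), searched
#'   to its left among `B3`;
#' * case 4 -- bottom line anchored at `b2` (rightmost global min), searched
#'   to its right among `B4`.
#'
#' The critical point minimizes the absolute slope to the anchor; remaining
#' ties are broken towards the point farthest from the anchor (smallest
#' index for the left-side cases 1 and 3, largest for the right-side cases
#' 2 and 4), so collinear candidates collapse onto the true hull vertex.
#' A candidate set that contains only the anchor itself yields slope 0
#' (no rotation possible on that side).
#'
#' Each candidate's band width `Ry` is the vertical extent of the band when
#' the parallel support pair is tilted to that case's slope: cases 1 and 4
#' share `Ry = 1 + (x(b2) - x(a1)) * min(|k1|, |k4|)` and cases 2 and 3
#' share `Ry = 1 + (x(a2) - x(b1)) * min(|k2|, |k3|)`, so the widths come
#' in equal pairs. Widths below 1 indicate a range-reducing rotation.
#'
#' This function is pure bookkeeping over slopes and is well defined for
#' any curve, including ones that fail [is_processable()] (where all four
#' widths are at least 1).
#'
#' @param norm A [normalize_curve()] result.
#' @param cand Candidate sets from [candidate_sets()].
#' @param anchors Anchors from [curve_anchors()].
#' @return An object of class `nuc_rotations`: a list of four candidate
#'   records, each with `case_id`, `anchor_top`, `anchor_bottom`,
#'   `critical_index`, `slope` (signed `k*`), `width` (`Ry`), and the band
#'   contact points `P1`, `P2` (top line) and `Q1`, `Q2` (bottom line) as
#'   indices.
#'
#' @examples
#' crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
#' sets <- index_sets(crv)
#' anc <- curve_anchors(sets)
#' nrm <- normalize_curve(crv)
#' critical_rotations(nrm, candidate_sets(sets, anc, 5), anc)
#' @export
critical_rotations <- function(norm, cand, anchors) {
  stopifnot(inherits(norm, "nuc_normalized"), inherits(cand, "nuc_candidates"),
            inherits(anchors, "nuc_anchors"))

  pick_critical <- function(set, anchor, pick) {
    s_abs <- abs(curve_slope(norm, set, anchor))
    ties <- set[s_abs == min(s_abs)]
    if (pick == "min") min(ties) else max(ties)
  }
  c1 <- pick_critical(cand$A3, anchors$a1, "min")
  c2 <- pick_critical(cand$A4, anchors$a2, "max")
  c3 <- pick_critical(cand$B3, anchors$b1, "min")
  c4 <- pick_critical(cand$B4, anchors$b2, "max")
  k <- c(curve_slope(norm, c1, anchors$a1),
         curve_slope(norm, c2, anchors$a2),
         curve_slope(norm, c3, anchors$b1),
         curve_slope(norm, c4, anchors$b2))

  dx14 <- norm$x[anchors$b2] - norm$x[anchors$a1]
  dx23 <- norm$x[anchors$a2] - norm$x[anchors$b1]
  ry14 <- 1 + dx14 * min(abs(k[1L]), abs(k[4L]))
  ry23 <- 1 + dx23 * min(abs(k[2L]), abs(k[3L]))
  ry <- c(ry14, ry23, ry23, ry14)

  crit <- c(c1, c2, c3, c4)
  a_top <- c(anchors$a1, anchors$a2, anchors$a2, anchors$a1)
  a_bot <- c(anchors$b2, anchors$b1, anchors$b1, anchors$b2)
  # band contacts per case: the rotating line holds anchor + critical point,
  # the following parallel line holds the opposite extreme alone
  p1 <- c(c1, anchors$a2, anchors$a2, anchors$a1)
  p2 <- c(anchors$a1, c2, anchors$a2, anchors$a1)
  q1 <- c(anchors$b2, anchors$b1, c3, anchors$b2)
  q2 <- c(anchors$b2, anchors$b1, anchors$b1, c4)

  out <- lapply(1:4, function(i) {
    list(case_id = i, anchor_top = a_top[i], anchor_bottom = a_bot[i],
         critical_index = crit[i], slope = k[i], width = ry[i],
         P1 = p1[i], P2 = p2[i], Q1 = q1[i], Q2 = q2[i])
  })
  structure(out, class = "nuc_rotations")
}

#' @export
as.data.frame.nuc_rotations <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(case = r$case_id, anchor_top = r$anchor_top,
               anchor_bottom = r$anchor_bottom, critical_index = r$critical_index,
               slope = r$slope, width = r$width)
  }))
}

#' @export
print.nuc_rotations <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Select the optimal rotation and build the shear specification
#'
#' Picks the case with the smallest band width `Ry*`; among width ties the
#' case with the smaller `|k*|` wins (a gentler shear achieving the same
#' band), and any residual tie goes to the smallest case index. The
#' cropping line -- the lower of the two parallel support lines -- passes
#' through the case's bottom anchor with slope `k*`, giving the intercept
#' `offset1 = -x(anchor_bottom) * k*` and the sampled line
#' `L(i) = k* x(i) + offset1`.
#'
#' @param cands A `nuc_rotations` object from [critical_rotations()].
#' @param norm The same normalized curve.
#' @param anchors The same anchors.
#' @return An object of class `nuc_shear`: a list with `k` (selected slope),
#'   `width` (`Ry*`), `selected_case`, `offset1`, `line` (the cropping line
#'   sampled at every `x(i)`), `anchor_top`, `anchor_bottom`, plus the full
#'   per-case `slopes` and `widths` vectors for tracing.
#'
#' @examples
#' crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
#' sets <- index_sets(crv)
#' anc <- curve_anchors(sets)
#' nrm <- normalize_curve(crv)
#' rot <- critical_rotations(nrm, candidate_sets(sets, anc, 5), anc)
#' select_rotation(rot, nrm, anc)
#' @export
select_rotation <- function(cands, norm, anchors) {
  stopifnot(inherits(cands, "nuc_rotations"), inherits(norm, "nuc_normalized"))
  widths <- vapply(cands, `[[`, numeric(1), "width")
  slopes <- vapply(cands, `[[`, numeric(1), "slope")
  ry_star <- min(widths)
  tied <- which(widths == ry_star)
  sel <- tied[order(abs(slopes[tied]), tied)][1L]
  k <- slopes[sel]
  bottom <- cands[[sel]]$anchor_bottom
  offset1 <- -norm$x[bottom] * k
  structure(list(
    k = k, width = ry_star, selected_case = sel, offset1 = offset1,
    line = k * norm$x + offset1,
    anchor_top = cands[[sel]]$anchor_top, anchor_bottom = bottom,
    slopes = slopes, widths = widths
  ), class = "nuc_shear")
}

#' @export
print.nuc_shear <- function(x, ...) {
  cat(sprintf("<shear: case %d, k* = %g, Ry* = %g, offset1 = %g>\n",
              x$selected_case, x$k, x$width, x$offset1))
  invisible(x)
}

#' Apply one shear transform to a curve
#'
#' Subtracts the cropping line from the normalized curve and maps the result
#' back to original units, i.e. removes the linear trend
#' `(k* x + offset1) / y_scale` from the values. Frequencies are returned
#' unchanged; the minimum value is preserved because the cropping line
#' touches the curve at the bottom anchor; the value range shrinks to
#' `Ry*` times its previous extent.
#'
#' @param curve The [spectral_curve()] the spec was computed from.
#' @param spec A `nuc_shear` from [select_rotation()].
#' @return A new [spectral_curve()].
#'
#' @examples
#' crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
#' sets <- index_sets(crv)
#' anc <- curve_anchors(sets)
#' nrm <- normalize_curve(crv)
#' spec <- select_rotation(critical_rotations(nrm, candidate_sets(sets, anc, 5), anc),
#'                         nrm, anc)
#' shear_once(crv, spec)$value   # 0 2.5 0 2.5 0
#' @export
shear_once <- function(curve, spec) {
  stopifnot(inherits(curve, "spectral_curve"), inherits(spec, "nuc_shear"))
  vr <- value_range(curve)
  if (vr == 0) {
    nuc_abort("cannot shear a flat curve", class = "nuc_degenerate_error")
  }
  spectral_curve(curve$frequency, curve$value - spec$line * vr)
}
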