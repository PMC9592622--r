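---
title: "The narrow undulation constraint: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The narrow undulation constraint: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuc)
```

## The problem

A THz-TDS absorption or extinction curve typically combines a large smooth
trend with small local undulation, and it is the undulation that carries
the discriminative signal for pattern recognition. Rasterized naively, the
curve occupies a tall image that is almost entirely empty; a CNN trained on
such images spends most of its capacity on blank area. The narrow
undulation constraint (NUC) shrinks the value range before rasterization
by repeatedly shearing the curve inside the narrowest pair of parallel
support lines reachable from its global extremes, so that at a fixed
value-per-pixel quantization the image height shrinks proportionally.

NUC is *not* a smoother or a baseline-correction method in the usual
chemometric sense: no point's relationship to its neighbours is altered by
anything other than the subtraction of a straight line per pass, and the
method makes no assumption about the noise distribution.

## One pass in detail

Each pass of `nuc()` operates on the curve normalized into the unit square
(`normalize_curve()`; x from frequency, y from value, both affine). With
`a1 <= a2` the leftmost/rightmost global-maximum indices and `b1 <= b2` the
global-minimum ones:

1. **Adaptation test.** The pass proceeds only if
   `(a1 - b2) * (b1 - a2) < 0`, i.e. the maxima lie entirely left or
   entirely right of the minima. Interleaved or flat curves are fixed
   points. The two factor orderings printed in the literature are
   algebraically identical; a unit test asserts this on random curves.
2. **Candidate filtering.** A support line rotating about an anchor can
   only stop at a convex-hull contact. On the top side these are the
   endpoints, local maxima and bumps (locally concave interior points of
   strictly monotone runs); on the bottom side the endpoints, local minima
   and pits. `classify_points()` labels points by strict neighbour
   comparisons, so plateaus and equal-increment runs drop out as `plain`
   automatically.
3. **Critical slopes.** For each of the four cases the candidate with the
   smallest absolute slope to the anchor is the touch point; the slope of a
   candidate set collapsed to the anchor itself is defined as 0 (that case
   then cannot rotate, its band width stays 1). Ties in absolute slope are
   collinear candidates; the outermost one (smallest index on the left
   cases, largest on the right cases) is taken, which is the true hull
   vertex.
4. **Band selection.** The case widths come in forced pairs
   (`Ry1 = Ry4`, `Ry2 = Ry3`); the minimum `Ry*` wins, a width tie goes to
   the smaller `|k*|` (the gentler shear), and a residual tie to the
   smallest case index so the selection is deterministic.
5. **Shear.** The lower line, through the bottom anchor with slope `k*`,
   is subtracted in normalized coordinates and the result un-normalized.
   Frequencies are returned bit-identical; the global minimum value is
   preserved exactly (the subtracted line is zero at the bottom anchor by
   construction); the value range contracts by the factor `Ry*`.

### Coordinates, not indices

The width formula multiplies `min |k|` by the *normalized x-coordinate*
difference of the two anchors, and the cropping-line intercept is
`-x(anchor) * k*`. A formulation in raw index differences agrees in sign —
and, under uniform sampling, up to a positive rescaling that leaves the
argmin unchanged — but only the coordinate form makes `Ry*` equal the
achieved normalized range, and only it is correct under non-uniform
sampling. This package uses the coordinate form throughout; the worked
`[0, 3, 1, 4, 2]` example in the README, where `Ry* = 0.625` and the range
contracts from 4 to exactly `0.625 * 4 = 2.5`, exercises it.

## Termination

In exact arithmetic every processable pass has `Ry* < 1` strictly: the
adaptation test forces the active anchors away from the curve ends, so the
relevant candidate slopes cannot vanish, and the range decreases
geometrically while the anchor indices migrate. In floating point a
different failure mode appears, which we found by property testing: after a
few passes two maxima can become equal to within one ulp, leaving a
candidate slope of order 1e-16 and `Ry* = 1 - 1e-16` — a shear that changes
nothing, alternating between two anchor configurations forever. `nuc()`
therefore stops (reason `"no reducing rotation"`) whenever a shear fails to
*strictly* reduce the value range, before recording the iteration. This
preserves the trace invariant that recorded ranges strictly decrease and
makes the output a genuine fixed point: re-running `nuc()` on any output
performs zero iterations. `max_iter` (default 100) remains as a final
backstop with a warning; the test suite never reaches it on curves up to
n = 200.

## Tunable parameters

* `tol` (default 0, value units): the equality threshold for value
  comparisons in classification and in global-extreme membership. The
  default reproduces exact strict inequalities; a small positive value is
  appropriate when an instrument quantizes values and plateaus are only
  approximate. It does not affect the slope computations themselves.
* `max_iter` (default 100): backstop iteration cap, see above.
* `raster_spec(pixels_per_value_unit, pixels_per_sample)`: the
  quantization of the output image. Height is
  `ceiling(range * pixels_per_value_unit)` with a relative guard of 1e-9
  inside the ceiling so that exactly representable products (e.g.
  0.045 × 10⁴ = 450) do not round up through floating noise; a flat curve
  gets a single row. There is no padding: the image is exactly the curve's
  bounding box, top row = maximum value.

## The oracle

The fast search is validated against an independent brute-force module
that shares no code with it: `convex_hull_chain()` (full monotone chain,
collinear vertices excluded at a 1e-12 cross-product tolerance),
`support_slope_exhaustive()` (support slope by scanning *every* point on a
side, no candidate filtering), and `min_vertical_band()` (the globally
narrowest vertical band over all slopes, found by evaluating the piecewise
linear width at every pairwise slope, O(N³) by design). The tests assert,
over a thousand random curves, that each filtered critical slope equals the
exhaustive support slope, that the selected band contains all points with
contact on both lines, that its contacts lie on the hull boundary, and that
neither one pass nor the full iteration ever beats the global band width —
the latter because every pass subtracts a line, so a complete run is one
composite linear detrend.

## Synthetic data: what it does and does not emulate

No public THz spectra accompany the method, so all testing rests on
generators whose structure is known by construction:

* `noisy_line(n = 21, seed, noise_amp = 1)` — an integer ramp plus uniform
  [0, noise_amp] noise: the canonical "strong trend, small undulation"
  case. The 21-point default matches the simulation scale the method was
  designed around.
* `ordered_extremes(pattern, n = 30, seed)` — curves realizing any of the
  14 orderings of `a1, a2, b1, b2`, built by placing the extremes at drawn
  indices and filling the rest with uniform noise strictly inside the
  range, then self-verifying the computed anchors (so the generator cannot
  drift from the anchor definitions). These drive the adaptation analysis:
  orderings with `b2 < a1` or `a2 < b1` must give a reducing band on the
  corresponding case pair, all others must not.
* `shape_curve(kind, ...)` — deterministic edge cases: exact lines
  (degenerate hull), plateaus (tie handling), V shapes (unprocessable),
  sine-on-trend (many extremes).

These emulate the *geometry* the algorithm depends on — anchor orderings,
hull structure, trend-to-undulation ratio — with continuous noise, so exact
value ties occur with probability zero. They do not emulate physical line
shapes (Lorentzian absorption, scattering baselines) or instrument
quantization. Consequently a passing suite demonstrates geometric
correctness of the search and the transform, not fitness of NUC as a
preprocessing choice for any particular material.

One genuine gap is worth stating plainly: for curves with *exact* interior
plateaus the candidate filter can miss the true support contact (a plateau
endpoint is `plain` — neither a local maximum nor a bump — yet can carry
the hull edge; `[0, 2, 2, 3]` is the smallest example). The filtered and
exhaustive searches then disagree and the selected "band" may clip a
point. Measured data with continuous noise never hits this; if in doubt,
a tiny `tol` or pre-jitter removes exact ties.

## Problem sizes in the checked properties

The test suite runs the full property set at: 14 × 100 ordered-extreme
curves (n = 30) for the adaptation table; 1000 mixed random curves
(n ∈ [3, 100]) for oracle equivalence; 200 noisy-ramp runs (n = 21) for
monotone range reduction, minimum preservation and the global-band lower
bound; and 300 mixed curves up to n = 200 for termination and the
fixed-point property. The acceptance script reports the extreme band
widths over 100 curves per ordering at n = 30. These sizes were chosen to
exercise every branch (including singleton candidate sets, boundary
anchors and equal-width ties) while keeping the whole suite fast enough to
run on every change.

## Known limitations

* Exact-tie plateaus, as above.
* NUC removes only what a sequence of straight-line subtractions can
  remove; a curved baseline is deliberately out of scope, as are
  smoothing-type pretreatments (Savitzky–Golay, MSC, median filtering).
* The per-pass search is restricted to the four anchored rotations; it is
  not the globally optimal band (`min_vertical_band()` exists precisely to
  quantify that gap, and the iteration closes much of it but is bounded
  below by the global band width of the original curve).
* Processed curves are pretreatment output for classification, not
  corrected spectra: values at individual frequencies are not preserved,
  only the undulation structure is.
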