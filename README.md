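# nuc — narrow undulation constraint pretreatment for spectral curves

Terahertz absorption and extinction spectra often ride on a large, smooth
trend (e.g. scattering baselines) while the information that distinguishes
samples lives in small local undulation. When such a curve is rasterized
into an image for a convolutional neural network, almost all of the pixel
budget goes into empty space above and below the curve. `nuc` implements
the **narrow undulation constraint (NUC)** pretreatment: it compresses the
value range of a sampled curve as far as a sequence of anchored shear
transforms allows, while leaving the undulation — and the frequency axis —
untouched.

## The method

Given a curve with samples (f_i, v_i), i = 1..N, normalize it into the unit
square (x, y ∈ [0, 1]). Let a1 ≤ a2 be the leftmost/rightmost indices
attaining the global maximum and b1 ≤ b2 those attaining the global minimum.
The curve is *processable* iff

    (a1 − b2)(b1 − a2) < 0,

i.e. both maxima lie strictly on one side of both minima. If so, consider
four rotations of a pair of parallel support lines, each anchored at one
extreme (a1, a2, b1, b2) and rotated until it first touches the curve again.
The touch point is found by comparing slopes to a filtered candidate set —
the endpoints plus the local maxima and "bump" (locally concave) points for
the top line, local minima and "pit" (locally convex) points for the bottom
line — because only those can be convex-hull contacts. Case i yields a slope
k_i\* and a band of vertical extent

    Ry_1 = Ry_4 = 1 + (x(b2) − x(a1)) · min(|k_1*|, |k_4*|)
    Ry_2 = Ry_3 = 1 + (x(a2) − x(b1)) · min(|k_2*|, |k_3*|).

The narrowest band Ry\* = min_i Ry_i (< 1 exactly when the curve is
processable) is selected, the lower line — through the bottom anchor with
slope k\* — is subtracted in normalized coordinates, and the result is mapped
back to original units. The new value range is Ry\* times the old one and the
minimum value is preserved. The pass is repeated until the extremes
interleave, giving a fixed point of the transform.

The package also ships an independent brute-force oracle (full monotone-chain
convex hull, exhaustive support-slope search, global minimum vertical band)
used by the test suite to validate the fast filtered search, seeded synthetic
curve generators, CSV/TSV spectra I/O, a curve-to-image rasterizer with
pixel-budget accounting, and a small CLI.

## Worked example

```r
library(nuc)
crv <- spectral_curve(0:4, c(0, 3, 1, 4, 2))
res <- nuc(crv, verbose = TRUE)
#> iteration 1: case 1, k* = 0.5, Ry* = 0.625, range 4 -> 2.5
res$curve$value
#> [1] 0.0 2.5 0.0 2.5 0.0
print(res$trace)
#> <nuc trace: 1 iteration(s), stopped because adaption check failed>
#>   1: case 1, k* = 0.5, Ry* = 0.625, range 4 -> 2.5
```

The curve's maximum (index 4) lies right of its minimum (index 1), so it is
processable. Rotating the top line about the maximum meets the curve at
index 2 with slope 0.5; the parallel band through the minimum has vertical
extent 0.625, so one shear contracts the range from 4 to 2.5 = 0.625 × 4.
The output's extremes interleave (maxima at {2, 4}, minima at {1, 3, 5}),
so the iteration stops: the result is a fixed point.

The pixel payoff at a fixed quantization (here 2 pixels per value unit):

```r
px <- raster_spec(pixels_per_value_unit = 2)
image_dims(5, value_range(crv), px)$total_pixels        # 40
image_dims(5, value_range(res$curve), px)$total_pixels  # 25
rasterize_curve(res$curve, px, "curve.pgm")             # plain-text PGM image
```

The same operations are available from a shell via the installed script
(`system.file("cli", "nuc", package = "nuc")`): `nuc simulate`, `nuc run`,
`nuc classify`, `nuc rasterize` — see `?nuc_main`.

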