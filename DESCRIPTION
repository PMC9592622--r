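Package: nuc
Title: Narrow Undulation Constraint Pretreatment for Sampled Spectral Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pretreats sampled absorption or extinction spectra (for example
    terahertz time-domain spectroscopy curves) by the narrow undulation
    constraint: the curve is normalized into the unit square, the narrowest
    pair of parallel support lines reachable by rotations anchored at its
    global extremes is found via a convex-hull-guided slope search, and a
    vertical shear compresses the value range while preserving the curve's
    undulation; the search-and-shear step is iterated to a fixed point.
    Includes a brute-force geometric oracle (full monotone-chain convex hull,
    exhaustive support slopes, global minimum vertical band) used for
    validation, seeded synthetic-curve generators, spectra CSV/TSV input and
    output, a curve-to-image rasterizer with pixel-budget reporting for
    convolutional-network input preparation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
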