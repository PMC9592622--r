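test_that("the monotone chain finds hull vertices and drops collinear boundary points", {
  # trapezoid with an interior point: vertices are the four extremes
  nrm <- normalize_curve(spectral_curve(0:4, c(0, 1, 0.5, 1, 0)))
  h <- convex_hull_chain(nrm)
  expect_setequal(h$vertices, c(1L, 2L, 4L, 5L))
  expect_false(h$degenerate)

  # worked example: point 3 lies exactly on the lower hull edge and is excluded
  h1 <- convex_hull_chain(normalize_curve(e1_curve()))
  expect_setequal(h1$vertices, c(1L, 2L, 4L, 5L))
  expect_equal(h1$lower, c(1L, 5L))

  hline <- convex_hull_chain(normalize_curve(spectral_curve(0:9, 2 * (0:9))))
  expect_true(hline$degenerate)
  expect_equal(hline$line_slope, 1)
})

test_that("every point lies inside or on the hull on random curves", {
  for (seed in 1:30) {
    crv <- mixed_curve(seed)
    if (value_range(crv) == 0) next
    nrm <- normalize_curve(crv)
    h <- convex_hull_chain(nrm)
    if (h$degenerate) next
    v <- h$vertices
    m <- length(v)
    for (i in seq_along(nrm$x)) {
      crosses <- vapply(seq_len(m), function(j) {
        a <- v[j]; b <- v[if (j == m) 1L else j + 1L]
        (nrm$x[b] - nrm$x[a]) * (nrm$y[i] - nrm$y[a]) -
          (nrm$y[b] - nrm$y[a]) * (nrm$x[i] - nrm$x[a])
      }, numeric(1))
      expect_true(all(crosses >= -1e-12))   # CCW hull: inside means left of every edge
    }
  }
})

test_that("exhaustive support slopes match the hand examples", {
  nrm <- normalize_curve(e1_curve())
  expect_equal(support_slope_exhaustive(nrm, 4, "left", "top"), 0.5)
  lnrm <- normalize_curve(spectral_curve(0:4, 0:4))
  expect_equal(support_slope_exhaustive(lnrm, 5, "left", "top"), 1)
  expect_equal(support_slope_exhaustive(nrm, 1, "left", "bottom"), 0)  # empty side
})

test_that("filtered critical slopes equal the exhaustive support slopes", {
  for (seed in 1:150) {
    crv <- mixed_curve(seed)
    if (!is_processable(crv)) next
    pl <- rotation_pipeline(crv)
    anc <- pl$anchors
    k <- vapply(pl$rots, `[[`, numeric(1), "slope")
    expect_equal(k[1], support_slope_exhaustive(pl$norm, anc$a1, "left", "top"))
    expect_equal(k[2], support_slope_exhaustive(pl$norm, anc$a2, "right", "top"))
    expect_equal(k[3], support_slope_exhaustive(pl$norm, anc$b1, "left", "bottom"))
    expect_equal(k[4], support_slope_exhaustive(pl$norm, anc$b2, "right", "bottom"))
  }
})

test_that("the global minimum vertical band matches hand-computed optima", {
  b <- min_vertical_band(normalize_curve(e1_curve()))
  expect_equal(b$slope, 0.5)
  expect_equal(b$width, 0.625)

  bl <- min_vertical_band(normalize_curve(spectral_curve(0:4, 0:4)))
  expect_equal(bl$width, 0)
  expect_true(bl$degenerate)
  expect_equal(bl$slope, 1)

  bv <- min_vertical_band(normalize_curve(spectral_curve(0:2, c(1, 0, 1))))
  expect_equal(bv$slope, 0)
  expect_equal(bv$width, 1)
})

test_that("the anchored band never beats the global band and touches the hull", {
  for (seed in 1:50) {
    crv <- mixed_curve(seed)
    if (!is_processable(crv)) next
    pl <- rotation_pipeline(crv)
    band <- min_vertical_band(pl$norm)
    expect_gte(pl$spec$width, band$width - 1e-9)

    hull <- convex_hull_chain(pl$norm)
    sel <- pl$rots[[pl$spec$selected_case]]
    for (i in unique(c(sel$P1, sel$P2, sel$Q1, sel$Q2))) {
      expect_true(on_hull_boundary(pl$norm, hull, i))
    }
  }
})
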