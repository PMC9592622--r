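test_that("candidate sets keep only hull-capable points outside the anchors", {
  crv <- e1_curve()
  sets <- index_sets(crv)
  cand <- candidate_sets(sets, curve_anchors(sets), 5)
  expect_equal(cand$A3, c(1L, 2L))
  expect_equal(cand$A4, 5L)
  expect_equal(cand$B3, 1L)
  expect_equal(cand$B4, c(3L, 5L))

  mono <- spectral_curve(0:4, 0:4)
  msets <- index_sets(mono)
  mcand <- candidate_sets(msets, curve_anchors(msets), 5)
  expect_equal(unname(lengths(mcand)), rep(1L, 4))
  expect_equal(mcand$A3, 1L)
  expect_equal(mcand$A4, 5L)

  # a1 = 1 collapses the left candidate set to the endpoint alone
  left <- spectral_curve(0:3, c(4, 1, 3, 0))
  lsets <- index_sets(left)
  expect_equal(candidate_sets(lsets, curve_anchors(lsets), 4)$A3, 1L)
})

test_that("slopes are finite, signed, and zero for self-pairs", {
  nrm <- normalize_curve(e1_curve())
  expect_equal(curve_slope(nrm, 2, 4), 0.5)
  expect_equal(curve_slope(nrm, 4, 4), 0)
  expect_equal(curve_slope(normalize_curve(spectral_curve(0:4, 0:4)), 1, 5), 1)
})

test_that("critical rotations find the support slopes of the worked example", {
  pl <- rotation_pipeline(e1_curve())
  df <- as.data.frame(pl$rots)
  expect_equal(df$critical_index, c(2L, 5L, 1L, 5L))
  expect_equal(df$slope, c(0.5, -2, 0, 0.5))
  expect_equal(df$width, c(0.625, 1, 1, 0.625))
})

test_that("a perfect line yields the diagonal rotation", {
  pl <- rotation_pipeline(spectral_curve(0:4, 0:4))
  df <- as.data.frame(pl$rots)
  expect_equal(df$slope, c(1, 0, 0, 1))
  expect_equal(df$critical_index, c(1L, 5L, 1L, 5L))
  expect_equal(pl$spec$width, 0)
  expect_equal(pl$spec$k, 1)
})

test_that("an anchor at the boundary degenerates its case to no rotation", {
  pl <- rotation_pipeline(spectral_curve(0:3, c(4, 1, 3, 0)))
  df <- as.data.frame(pl$rots)
  expect_equal(df$critical_index[1], 1L)
  expect_equal(df$slope[1], 0)
  expect_equal(df$width[1], 1)   # Ry1 = 1 + (x(b2)-x(a1)) * min(0, |k4|)
})

test_that("rotation selection prefers the narrowest band, then the gentler slope", {
  pl <- rotation_pipeline(e1_curve())
  expect_equal(pl$spec$width, 0.625)
  expect_equal(pl$spec$k, 0.5)
  expect_equal(pl$spec$selected_case, 1L)   # Ry1 = Ry4, |k1| = |k4|: lowest case wins
  expect_equal(pl$spec$offset1, 0)          # cropping line through x(b2) = 0

  # all-zero slopes: identity shear, unit width
  fake <- structure(lapply(1:4, function(i) {
    list(case_id = i, anchor_top = 2L, anchor_bottom = 1L, critical_index = 1L,
         slope = 0, width = 1, P1 = 1L, P2 = 1L, Q1 = 1L, Q2 = 1L)
  }), class = "nuc_rotations")
  spec <- select_rotation(fake, normalize_curve(e1_curve()), NULL)
  expect_equal(spec$width, 1)
  expect_equal(spec$k, 0)
})

test_that("the widths come in equal pairs and bound the achieved band", {
  for (seed in 1:50) {
    crv <- mixed_curve(seed)
    if (!is_processable(crv)) next
    pl <- rotation_pipeline(crv)
    w <- pl$spec$widths
    expect_equal(w[1], w[4])
    expect_equal(w[2], w[3])
    expect_lt(pl$spec$width, 1)   # processable implies a reducing rotation
    expect_true(band_is_support(pl$norm, pl$spec))
  }
})

test_that("shear removes the cropping line and preserves frequency and minimum", {
  crv <- e1_curve()
  pl <- rotation_pipeline(crv)
  out <- shear_once(crv, pl$spec)
  expect_equal(out$value, c(0, 2.5, 0, 2.5, 0))
  expect_identical(out$frequency, crv$frequency)

  line <- spectral_curve(0:4, 0:4)
  expect_equal(shear_once(line, rotation_pipeline(line)$spec)$value, rep(0, 5))

  # identity spec leaves the curve untouched
  ident <- structure(list(k = 0, width = 1, selected_case = 1L, offset1 = 0,
                          line = rep(0, 5), anchor_top = 4L, anchor_bottom = 1L,
                          slopes = rep(0, 4), widths = rep(1, 4)),
                     class = "nuc_shear")
  expect_equal(shear_once(crv, ident)$value, crv$value)
})

test_that("shear contracts the range by exactly the selected width", {
  for (seed in 1:40) {
    crv <- mixed_curve(seed)
    if (!is_processable(crv)) next
    pl <- rotation_pipeline(crv)
    out <- shear_once(crv, pl$spec)
    expect_identical(out$frequency, crv$frequency)
    expect_equal(min(out$value), min(crv$value), tolerance = 1e-9)
    expect_equal(value_range(out), pl$spec$width * value_range(crv),
                 tolerance = 1e-9)
  }
})
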