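test_that("interior points are classified by strict neighbour comparisons", {
  expect_equal(classify_points(e1_curve()),
               c("plain", "local_max", "local_min", "local_max", "plain"))
  # strictly decreasing increments on a rising run are bumps
  expect_equal(classify_points(spectral_curve(0:4, c(0, 2, 3, 3.5, 1))),
               c("plain", "bump", "bump", "local_max", "plain"))
  # equal-increment runs and plateaus are plain
  expect_equal(classify_points(spectral_curve(0:2, c(5, 5, 5))), rep("plain", 3))
  expect_equal(classify_points(spectral_curve(0:4, c(0, 2, 2, 2, 1))),
               rep("plain", 5))
  # falling runs: concave points are bumps, convex points are pits
  expect_equal(classify_points(spectral_curve(0:3, c(4, 3, 1, 0))),
               c("plain", "bump", "pit", "plain"))
})

test_that("curves with fewer than 3 samples are rejected", {
  expect_error(spectral_curve(0:1, c(0, 1)), class = "nuc_validation_error")
  expect_error(spectral_curve(c(0, 1, 1), c(0, 1, 2)), "duplicate frequency",
               class = "nuc_validation_error")
  expect_error(spectral_curve(0:2, c(0, NA, 2)), class = "nuc_validation_error")
})

test_that("index sets collect global extremes and labeled points", {
  s <- index_sets(e1_curve())
  expect_equal(s$A, 4L)
  expect_equal(s$B, 1L)
  expect_equal(s$A1, c(2L, 4L))
  expect_equal(s$B1, 3L)
  expect_length(s$A2, 0)
  expect_length(s$B2, 0)

  flat <- index_sets(spectral_curve(0:3, rep(2, 4)))
  expect_equal(flat$A, 1:4)
  expect_equal(flat$B, 1:4)
  expect_length(flat$A1, 0)

  mono <- index_sets(spectral_curve(0:3, 0:3))
  expect_equal(mono$A, 4L)
  expect_equal(mono$B, 1L)
  expect_true(all(lengths(mono[c("A1", "A2", "B1", "B2")]) == 0))
})

test_that("anchors are the extreme indices of A and B", {
  expect_equal(unlist(curve_anchors(index_sets(e1_curve()))),
               c(a1 = 4L, a2 = 4L, b1 = 1L, b2 = 1L))
  expect_equal(unlist(curve_anchors(index_sets(spectral_curve(0:4, c(0, 3, 0, 3, 0))))),
               c(a1 = 2L, a2 = 4L, b1 = 1L, b2 = 5L))
  expect_equal(unlist(curve_anchors(index_sets(spectral_curve(0:3, rep(1, 4))))),
               c(a1 = 1L, a2 = 4L, b1 = 1L, b2 = 4L))
})

test_that("the adaptation test accepts separated extremes and rejects interleaved or flat ones", {
  expect_true(is_processable(e1_curve()))
  expect_false(is_processable(spectral_curve(0:4, c(0, 3, 0, 3, 0))))
  expect_false(is_processable(spectral_curve(0:3, rep(2, 4))))
  expect_false(is_processable(spectral_curve(0:2, c(1, 0, 1))))
})

test_that("label classes are mutually exclusive and anchors ordered on random curves", {
  for (seed in 1:60) {
    crv <- mixed_curve(seed)
    labels <- classify_points(crv)
    sets <- index_sets(crv, labels = labels)
    pieces <- sets[c("A1", "A2", "B1", "B2")]
    for (i in 1:3) for (j in (i + 1):4) {
      expect_length(intersect(pieces[[i]], pieces[[j]]), 0)
    }
    anc <- curve_anchors(sets)
    expect_lte(anc$a1, anc$a2)
    expect_lte(anc$b1, anc$b2)
    # the two printed forms of the adaptation product agree
    expect_identical((anc$a1 - anc$b2) * (anc$b1 - anc$a2) < 0,
                     (anc$b2 - anc$a1) * (anc$a2 - anc$b1) < 0)
    # endpoints never get a non-plain label
    expect_equal(labels[c(1, length(crv))], c("plain", "plain"))
  }
})

test_that("the tolerance knob treats near-ties as equal", {
  crv <- spectral_curve(0:3, c(0, 1, 1 + 1e-12, 0))
  expect_equal(classify_points(crv)[2:3], c("bump", "local_max"))
  expect_equal(classify_points(crv, tol = 1e-9)[2:3], c("plain", "plain"))
  expect_equal(index_sets(crv, tol = 1e-9)$A, c(2L, 3L))
  expect_equal(index_sets(crv)$A, 3L)
})
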