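# Shared fixtures and small geometric checkers, all built in code.

e1_curve <- function() spectral_curve(0:4, c(0, 3, 1, 4, 2))

# Uniform-noise curve; values are continuous so exact ties have probability 0.
random_curve <- function(n, seed) {
  set.seed(seed)
  spectral_curve(0:(n - 1), stats::runif(n))
}

# A mixed pool of smooth and noisy shapes for property tests.
mixed_curve <- function(seed, n_max = 100) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  kind <- seed %% 3
  if (kind == 0) {
    noisy_line(max(n, 3), seed = seed, noise_amp = stats::runif(1, 0.2, 3))
  } else if (kind == 1) {
    shape_curve("sine_trend", n = max(n, 4), seed = seed,
                trend = stats::runif(1, 0.05, 0.5), noise_amp = stats::runif(1, 0, 0.5))
  } else {
    spectral_curve(0:(n - 1), stats::runif(n))
  }
}

# Full single-pass pipeline up to the shear spec.
rotation_pipeline <- function(curve, tol = 0) {
  sets <- index_sets(curve, tol = tol)
  anc <- curve_anchors(sets)
  norm <- normalize_curve(curve)
  cand <- candidate_sets(sets, anc, length(curve))
  rots <- critical_rotations(norm, cand, anc)
  list(sets = sets, anchors = anc, norm = norm, cand = cand, rots = rots,
       spec = select_rotation(rots, norm, anc))
}

# Is every normalized point inside the band [L, L + width], with contact
# (within tol) on both lines?
band_is_support <- function(norm, spec, tol = 1e-9) {
  r <- norm$y - spec$line
  all(r >= -tol) && all(r <= spec$width + tol) &&
    min(r) <= tol && max(r) >= spec$width - tol
}

# Does point i lie on the boundary of the hull (on a vertex or an edge)?
on_hull_boundary <- function(norm, hull, i, tol = 1e-9) {
  v <- hull$vertices
  if (i %in% v) return(TRUE)
  m <- length(v)
  for (j in seq_len(m)) {
    a <- v[j]; b <- v[if (j == m) 1L else j + 1L]
    cr <- (norm$x[b] - norm$x[a]) * (norm$y[i] - norm$y[a]) -
          (norm$y[b] - norm$y[a]) * (norm$x[i] - norm$x[a])
    within <- norm$x[i] >= min(norm$x[a], norm$x[b]) - tol &&
              norm$x[i] <= max(norm$x[a], norm$x[b]) + tol
    if (abs(cr) <= tol && within) return(TRUE)
  }
  FALSE
}

# Check computed anchors against an ordering pattern string.
pattern_holds <- function(pattern, anc) {
  groups <- strsplit(strsplit(pattern, "<", fixed = TRUE)[[1]], "=", fixed = TRUE)
  idx <- vapply(groups, function(g) anc[[g[1]]], numeric(1))
  for (g in seq_along(groups)) {
    if (!all(vapply(groups[[g]], function(tok) anc[[tok]] == idx[g], logical(1)))) {
      return(FALSE)
    }
  }
  all(diff(idx) > 0)
}
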