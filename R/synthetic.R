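# Run code under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Noisy ramp test curve
#'
#' The canonical simulation curve: an integer ramp `0, 1, ..., n-1` with an
#' independent uniform `[0, noise_amp]` value added to every sample. The
#' pretreatment extracts the noise undulation from the rising trend,
#' collapsing the range from about `n` to about `noise_amp`.
#'
#' @param n Number of samples (default 21).
#' @param seed Integer seed; the same `(n, seed, noise_amp)` always yields
#'   the same curve.
#' @param noise_amp Noise amplitude (default 1); 0 gives an exact line.
#' @return A [spectral_curve()] with frequencies `0:(n-1)`.
#'
#' @examples
#' noisy_line(21, seed = 1)
#' @export
noisy_line <- function(n = 21, seed = NULL, noise_amp = 1) {
  if (n < 3) nuc_abort("n must be at least 3")
  u <- with_local_seed(seed, stats::runif(n))
  spectral_curve(0:(n - 1), 0:(n - 1) + noise_amp * u)
}

# The 14 realizable orderings of the extreme anchors (a1, a2) and (b1, b2).
ordered_extremes_patterns <- c(
  "a1<a2<b1<b2", "a1<b1<a2<b2", "a1<b1<b2<a2", "b1<b2<a1<a2",
  "b1<a1<b2<a2", "b1<a1<a2<b2", "a1=a2<b1<b2", "b1<a1=a2<b2",
  "b1<b2<a1=a2", "b1=b2<a1<a2", "a1<b1=b2<a2", "a1<a2<b1=b2",
  "a1=a2<b1=b2", "b1=b2<a1=a2"
)

parse_extreme_pattern <- function(pattern) {
  groups <- strsplit(strsplit(pattern, "<", fixed = TRUE)[[1]], "=", fixed = TRUE)
  toks <- unlist(groups)
  if (!setequal(toks, c("a1", "a2", "b1", "b2")) || length(toks) != 4) {
    nuc_abort("pattern '%s' must order each of a1, a2, b1, b2 exactly once", pattern)
  }
  for (g in groups) {
    if (length(g) > 1 && !identical(sort(g), c("a1", "a2")) &&
        !identical(sort(g), c("b1", "b2"))) {
      nuc_abort("pattern '%s': '=' is only allowed within a1=a2 or b1=b2", pattern)
    }
  }
  pos <- function(tok) which(vapply(groups, function(g) tok %in% g, logical(1)))
  if (pos("a1") > pos("a2") || pos("b1") > pos("b2")) {
    nuc_abort("pattern '%s' violates a1 <= a2 or b1 <= b2", pattern)
  }
  groups
}

#' Random curve with a prescribed ordering of its extreme anchors
#'
#' Generates a curve whose anchors ([curve_anchors()]) realize a requested
#' ordering of `a1, a2, b1, b2`, e.g. `"a1<a2<b1<b2"` or
#' `"b1=b2<a1=a2"`. Construction: the pattern's slots are assigned to
#' randomly drawn distinct indices in order; those indices get the global
#' maximum (1) or minimum (0) and all remaining samples are filled with
#' uniform noise strictly inside (0, 1). The result is self-verified
#' against [curve_anchors()] and redrawn on failure (bounded retries), so
#' the generator cannot drift from the anchor definitions.
#'
#' @param pattern One of the 14 realizable ordering strings (see
#'   `nuc:::ordered_extremes_patterns`); `<` separates strictly increasing
#'   indices and `=` merges `a1=a2` or `b1=b2` into one index.
#' @param n Number of samples (default 30).
#' @param seed Integer seed for reproducibility.
#' @param max_tries Redraw bound for the self-verification (default 20).
#' @return A [spectral_curve()] with frequencies `0:(n-1)`.
#'
#' @examples
#' crv <- ordered_extremes("a1<a2<b1<b2", n = 30, seed = 7)
#' curve_anchors(index_sets(crv))
#' @export
ordered_extremes <- function(pattern, n = 30, seed = NULL, max_tries = 20) {
  groups <- parse_extreme_pattern(pattern)
  m <- length(groups)
  if (n < m + 1) nuc_abort("n = %d too small for pattern '%s'", n, pattern)
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      idx <- sort(sample.int(n, m))
      v <- 0.05 + 0.9 * stats::runif(n)
      for (g in seq_len(m)) {
        v[idx[g]] <- if (groups[[g]][1] %in% c("a1", "a2")) 1 else 0
      }
      crv <- spectral_curve(0:(n - 1), v)
      anc <- curve_anchors(index_sets(crv))
      want <- list(a1 = NA_integer_, a2 = NA_integer_,
                   b1 = NA_integer_, b2 = NA_integer_)
      for (g in seq_len(m)) for (tok in groups[[g]]) want[[tok]] <- idx[g]
      if (identical(unlist(anc), unlist(want))) return(crv)
    }
    nuc_abort("could not realize pattern '%s' in %d tries", pattern, max_tries)
  })
}

#' Deterministic edge-case curve shapes
#'
#' Fixture shapes exercising specific code paths:
#'
#' * `sine_trend` -- a rising line plus a sinusoid: a smooth curve with
#'   several local extremes riding on a trend;
#' * `plateau` -- ramp up, flat top, partial descent: interior plateau
#'   points are labeled `plain` by [classify_points()];
#' * `collinear` -- an exact straight line: degenerate convex hull, and a
#'   single pretreatment pass collapses it to a constant;
#' * `v_shape` -- symmetric V: both endpoints share the global maximum, so
#'   the adaptation test fails and the curve is returned unchanged.
#'
#' @param kind One of `"sine_trend"`, `"plateau"`, `"collinear"`,
#'   `"v_shape"`.
#' @param n Number of samples.
#' @param seed Integer seed, used only by `sine_trend` when
#'   `noise_amp > 0`.
#' @param trend,amplitude,cycles,noise_amp `sine_trend` parameters: linear
#'   slope per sample, sine amplitude, whole periods over the support, and
#'   uniform-noise amplitude.
#' @param plateau_width Number of equal-valued samples at the top of the
#'   `plateau` shape.
#' @param intercept,slope Line parameters for `collinear`.
#' @return A [spectral_curve()] with frequencies `0:(n-1)`.
#'
#' @examples
#' shape_curve("v_shape", n = 3)$value   # 1 0 1
#' @export
shape_curve <- function(kind = c("sine_trend", "plateau", "collinear", "v_shape"),
                        n = 30, seed = NULL,
                        trend = 0.2, amplitude = 1, cycles = 2, noise_amp = 0,
                        plateau_width = max(2L, n %/% 3L),
                        intercept = 0, slope = 1) {
  kind <- match.arg(kind)
  if (n < 3) nuc_abort("n must be at least 3")
  t <- 0:(n - 1)
  v <- switch(kind,
    sine_trend = trend * t + amplitude * sin(2 * pi * cycles * t / (n - 1)) +
      noise_amp * with_local_seed(seed, stats::runif(n)),
    plateau = {
      w <- min(plateau_width, n - 2L)
      up <- n - w - 1L                      # samples strictly before the flat top
      c(seq(0, 1, length.out = up + 1L)[seq_len(up)], rep(1, w),
        seq(1, 0.5, length.out = n - up - w + 1L)[-1L])
    },
    collinear = intercept + slope * t,
    v_shape = abs(seq(-1, 1, length.out = n))
  )
  spectral_curve(t, v)
}
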