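# ---- spectra files ---------------------------------------------------------

read_spectrum_table <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) nuc_abort("file not found: %s", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2) nuc_abort("%s: need a frequency column plus at least one value column", path)
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) | !is.finite(num[[j]]))
    if (length(bad)) {
      nuc_abort("%s: non-numeric or non-finite cell in column '%s' at data row %d",
                path, names(df)[j], bad[1L])
    }
  }
  f <- num[[1L]]
  d <- diff(f)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    if (d[row - 1L] == 0) nuc_abort("%s: duplicate frequency at data row %d", path, row)
    nuc_abort("%s: frequencies not strictly increasing at data row %d", path, row)
  }
  if (length(f) < 3) nuc_abort("%s: need at least 3 samples (got %d)", path, length(f))
  c(list(frequency = f), num[-1L])
}

#' Read a two-column spectrum file
#'
#' Reads a CSV (or TSV) spectrum with a header row and two numeric columns,
#' frequency then value. Validation failures (non-numeric cells, unsorted
#' or duplicate frequencies, fewer than 3 samples) raise descriptive errors
#' naming the offending data row.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, or `"auto"` (default: by extension,
#'   `.tsv`/`.tab`/`.txt` are tab-separated).
#' @return A [spectral_curve()].
#'
#' @seealso [read_spectra()] for wide files with several value columns.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "tsv")) {
  cols <- read_spectrum_table(path, format)
  if (length(cols) != 2) {
    nuc_abort("%s: expected exactly 2 columns, got %d (use read_spectra for wide files)",
              path, length(cols))
  }
  spectral_curve(cols$frequency, cols[[2L]])
}

#' Read a wide spectrum file with a shared frequency axis
#'
#' @inheritParams read_spectrum
#' @return A named list of [spectral_curve()]s, one per value column.
#' @export
read_spectra <- function(path, format = c("auto", "csv", "tsv")) {
  cols <- read_spectrum_table(path, format)
  f <- cols$frequency
  lapply(cols[-1L], function(v) spectral_curve(f, v))
}

#' Write a spectrum file
#'
#' Writes a curve as a two-column CSV/TSV with header `frequency,value`.
#' Numbers are serialized with 17 significant digits, so reading the file
#' back reproduces the values bit-for-bit.
#'
#' @param curve A [spectral_curve()].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(curve, path, format = c("auto", "csv", "tsv")) {
  stopifnot(inherits(curve, "spectral_curve"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- c(paste("frequency", "value", sep = sep),
             paste(sprintf("%.17g", curve$frequency),
                   sprintf("%.17g", curve$value), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a pretreatment trace as JSON
#'
#' Writes the per-iteration record of a [nuc()] run -- anchors, selected
#' case, slope `k*`, width `Ry*`, offset, and value ranges -- plus the
#' iteration count and termination reason.
#'
#' @param trace A `nuc_trace` (from `nuc(...)$trace`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nuc_trace"))
  its <- lapply(trace$iterations, function(it) {
    list(iteration = it$iteration,
         anchors = list(a1 = it$anchors$a1, a2 = it$anchors$a2,
                        b1 = it$anchors$b1, b2 = it$anchors$b2),
         selected_case = it$selected_case,
         k = it$k, Ry = it$Ry, offset1 = it$offset1,
         range_before = it$range_before, range_after = it$range_after)
  })
  jsonlite::write_json(
    list(n_iterations = trace$n_iterations, reason = trace$reason,
         warning = trace$warning, iterations = its),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- rasterization ---------------------------------------------------------

#' Rasterization specification
#'
#' Fixes the value-to-pixel quantization used to turn a curve into an image
#' for CNN input: `pixels_per_value_unit` vertical pixels per unit of value
#' (e.g. 100 pixels per 0.01 absorption means 10000 per unit) and
#' `pixels_per_sample` horizontal pixels per sample.
#'
#' @param pixels_per_value_unit Positive real: vertical pixels per value unit.
#' @param pixels_per_sample Positive integer: image columns per sample
#'   (default 1).
#' @return An object of class `nuc_raster_spec`.
#' @export
raster_spec <- function(pixels_per_value_unit, pixels_per_sample = 1L) {
  if (pixels_per_value_unit <= 0 || pixels_per_sample < 1) {
    nuc_abort("raster spec parameters must be positive")
  }
  structure(list(pixels_per_value_unit = pixels_per_value_unit,
                 pixels_per_sample = as.integer(pixels_per_sample)),
            class = "nuc_raster_spec")
}

#' Image dimensions and pixel budget for a rasterized curve
#'
#' The image is exactly as wide as the sample count (times
#' `pixels_per_sample`) and as tall as the quantized value range:
#' `height = ceiling(value_range * pixels_per_value_unit)`, with a
#' single-row image for a flat curve. A small relative epsilon guards the
#' ceiling against floating noise so that, e.g., a range of 0.045 at 10000
#' pixels per unit gives exactly 450 rows. Compressing the value range
#' before rasterizing shrinks the pixel budget proportionally.
#'
#' @param n_samples Number of curve samples.
#' @param value_range Value range of the curve (non-negative).
#' @param spec A [raster_spec()].
#' @return A list with `width`, `height` and `total_pixels`.
#'
#' @examples
#' px <- raster_spec(pixels_per_value_unit = 100 / 0.01)
#' image_dims(50, 0.045, px)$total_pixels   # 22500
#' image_dims(50, 0.005, px)$total_pixels   # 2500
#' @export
image_dims <- function(n_samples, value_range, spec) {
  stopifnot(inherits(spec, "nuc_raster_spec"))
  if (n_samples < 1 || value_range < 0) nuc_abort("invalid raster dimensions")
  width <- as.integer(n_samples) * spec$pixels_per_sample
  h <- value_range * spec$pixels_per_value_unit
  height <- if (h <= 0) 1L else as.integer(ceiling(h - 1e-9 * max(1, h)))
  height <- max(height, 1L)
  list(width = width, height = height, total_pixels = width * height)
}

# Integer line rasterization (Bresenham) between two pixel coordinates;
# returns the visited (col, row) pairs including both endpoints.
bresenham <- function(c0, r0, c1, r1) {
  dc <- abs(c1 - c0); dr <- abs(r1 - r0)
  sc <- sign(c1 - c0); sr <- sign(r1 - r0)
  err <- dc - dr
  cols <- integer(dc + dr + 1L); rows <- integer(dc + dr + 1L)
  i <- 0L
  repeat {
    i <- i + 1L
    cols[i] <- c0; rows[i] <- r0
    if (c0 == c1 && r0 == r1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  cbind(col = cols[seq_len(i)], row = rows[seq_len(i)])
}

#' Rasterize a curve to a monochrome image
#'
#' Draws the curve as a polyline in a binary image whose dimensions come
#' from [image_dims()]: one column band per sample, the maximum value on
#' the top row (row 1, standard image orientation), consecutive sample
#' pixels joined by integer (Bresenham) line segments. The canonical output
#' format is plain-text PGM (`P2`, black curve on white); a `.png` path
#' writes PNG instead when the `png` package is available.
#'
#' @param curve A [spectral_curve()].
#' @param spec A [raster_spec()].
#' @param path Optional output path (`.pgm` or `.png`); omit to just get
#'   the matrix.
#' @return Invisibly, the image as an integer matrix (`height` rows by
#'   `width` columns, 1 = curve, 0 = background).
#'
#' @examples
#' m <- rasterize_curve(spectral_curve(0:4, c(0, 3, 1, 4, 2)),
#'                      raster_spec(pixels_per_value_unit = 2))
#' dim(m)   # 8 rows, 5 columns
#' @export
rasterize_curve <- function(curve, spec, path = NULL) {
  stopifnot(inherits(curve, "spectral_curve"), inherits(spec, "nuc_raster_spec"))
  n <- length(curve)
  vmax <- max(curve$value)
  dims <- image_dims(n, value_range(curve), spec)
  img <- matrix(0L, nrow = dims$height, ncol = dims$width)
  cols <- (seq_len(n) - 1L) * spec$pixels_per_sample + 1L
  rows <- pmin(pmax(ceiling((vmax - curve$value) * spec$pixels_per_value_unit), 1L),
               dims$height)
  rows <- as.integer(rows)
  for (i in seq_len(n - 1L)) {
    px <- bresenham(cols[i], rows[i], cols[i + 1L], rows[i + 1L])
    img[px[, c("row", "col"), drop = FALSE]] <- 1L
  }
  if (!is.null(path)) {
    if (tolower(tools::file_ext(path)) == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        nuc_abort("the 'png' package is required for PNG output")
      }
      png::writePNG(1 - img, path)   # curve black on white
    } else {
      write_pgm(img, path)
    }
  }
  invisible(img)
}

# Plain-text PGM (P2): 255 = background, 0 = curve. Diff-able fixture format.
write_pgm <- function(img, path) {
  body <- apply(255L - img * 255L, 1L, paste, collapse = " ")
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255", body), path)
  invisible(path)
}

# Parse a plain P2 PGM back into the 0/1 curve matrix (test helper).
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (lines[1L] != "P2") nuc_abort("%s: not a plain (P2) PGM file", path)
  tokens <- as.integer(unlist(strsplit(paste(lines[-1L], collapse = " "), "\\s+")))
  tokens <- tokens[!is.na(tokens)]
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  px <- tokens[-(1:3)]
  stopifnot(length(px) == w * h)
  matrix(as.integer(px < maxval / 2), nrow = h, ncol = w, byrow = TRUE)
}
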