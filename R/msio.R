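#' Single-channel image
#'
#' A 2-D raster of intensities in \[0, 1\] tagged with the illumination
#' channel it came from.  Stored as a plain numeric matrix (`row`, `col`,
#' 1-based, row 1 at the top) so it composes with base matrix operations.
#'
#' @param pixels numeric matrix of finite intensities.
#' @param channel_label one of `"white"`, `"red"`, `"green"`, `"blue"`,
#'   `"gray"`.
#' @export
channel_image <- function(pixels, channel_label = "gray") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(!is.finite(pixels)))
    stop("'pixels' must be a finite numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("'pixels' must be at least 1 x 1", call. = FALSE)
  channel_label <- match.arg(channel_label,
                             c("white", "red", "green", "blue", "gray"))
  structure(list(pixels = pixels, channel_label = channel_label),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d, range [%.3f, %.3f]\n",
              x$channel_label, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept a channel_image or a bare matrix wherever pixels are needed.
as_pixel_matrix <- function(img) {
  if (inherits(img, "channel_image")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a channel_image or numeric matrix", call. = FALSE)
}

#' Read a PNG or TIFF image
#'
#' Grayscale files become a [channel_image()]; colour files are returned as
#' an `rows x cols x 3` array of intensities in \[0, 1\] (any alpha plane is
#' dropped).
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param channel_label label attached when the file is single-channel.
#' @export
read_image <- function(path, channel_label = "gray") {
  if (!file.exists(path)) stop(sprintf("no such image file: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE))
  if (length(dim(a)) == 3 && dim(a)[3] >= 3) return(a[, , 1:3, drop = FALSE])
  if (length(dim(a)) == 3) a <- a[, , 1]
  channel_image(a, channel_label)
}

#' Write an image to PNG or TIFF
#'
#' @param raster a [channel_image()], numeric matrix, logical mask (written
#'   as 0/1), or `rows x cols x 3` array, all on the \[0, 1\] scale.
#' @param path destination (`.png`, `.tif`/`.tiff`); parent must exist.
#' @param bits bit depth for PNG output (8 or 16).
#' @export
write_image <- function(raster, path, bits = 8) {
  if (inherits(raster, "channel_image")) raster <- raster$pixels
  if (is.logical(raster)) raster <- raster * 1
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: '%s'", dirname(path)), call. = FALSE)
  raster <- clamp01(raster)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(raster, path, dpi = NULL,
                             asp = NULL, text = NULL,
                             metadata = NULL),
         tif = ,
         tiff = tiff::writeTIFF(raster, path, bits.per.sample = bits),
         stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE))
  if (ext == "png" && bits == 16) {
    # png::writePNG picks 8 bit for doubles; re-write via integer rounding
    png::writePNG(round(raster * 65535) / 65535, path)
  }
  invisible(path)
}

#' Convert an RGB raster to grayscale
#'
#' Weighted luminance with the standard video weights
#' (0.299, 0.587, 0.114), which sum to 1.
#'
#' @param rgb `rows x cols x 3` numeric array in \[0, 1\].
#' @return a [channel_image()] labelled `"gray"`.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("'rgb' must be a rows x cols x 3 array", call. = FALSE)
  w <- c(0.299, 0.587, 0.114)
  g <- matrix(w[1] * rgb[, , 1] + w[2] * rgb[, , 2] + w[3] * rgb[, , 3],
              dim(rgb)[1], dim(rgb)[2])
  channel_image(g, "gray")
}

# Classic 64-entry jet lookup table (dark blue -> blue -> cyan -> yellow ->
# red -> dark red), as used for pseudocolour display of scalar images.
jet_lut <- function(n = 64) {
  ramp <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))
  x <- seq(0, 1, length.out = n)
  r <- ramp(x, 3 / 8, 5 / 8) - ramp(x, 7 / 8, 9 / 8)
  g <- ramp(x, 1 / 8, 3 / 8) - ramp(x, 5 / 8, 7 / 8)
  b <- ramp(x, -1 / 8, 1 / 8) - ramp(x, 3 / 8, 5 / 8)
  cbind(r, g, b)
}

#' Jet pseudocolour rendering of a scalar image
#'
#' Maps intensities in \[0, 1\] through the classic 64-entry jet ramp
#' (linearly interpolated): 0 maps to dark blue, 1 to dark red.  Display
#' only — all quantitative analysis in this package runs on the scalar
#' intensities.
#'
#' @param img a [channel_image()] or numeric matrix with values in \[0, 1\].
#' @return `rows x cols x 3` numeric array.
#' @export
apply_jet_colormap <- function(img) {
  px <- as_pixel_matrix(img)
  if (min(px) < 0 || max(px) > 1) stop("intensities must lie in [0, 1]", call. = FALSE)
  lut <- jet_lut(64)
  pos <- px * 63 + 1
  lo <- floor(pos); hi <- ceiling(pos); fr <- pos - lo
  out <- array(0, c(nrow(px), ncol(px), 3))
  for (k in 1:3) {
    out[, , k] <- matrix(lut[lo, k] * (1 - fr) + lut[hi, k] * fr,
                         nrow(px), ncol(px))
  }
  out
}

#' Intensity histogram of a masked region
#'
#' Counts the intensities of the pixels selected by `region` into `n_bins`
#' equal bins spanning \[0, 1\], and records the region's mean and standard
#' deviation.  Used to compare the inside-TM and outside-TM (ear-canal wall)
#' intensity distributions per illumination channel.
#'
#' @param img a [channel_image()] or numeric matrix.
#' @param region logical matrix of the same dimensions, at least one `TRUE`.
#' @param n_bins number of bins (default 256).
#' @param region_label free-text label stored with the histogram.
#' @return a `region_histogram`: list with `bin_edges` (length
#'   `n_bins + 1`), `counts`, `region_label`, `mean`, `sd`.
#' @export
region_histogram <- function(img, region, n_bins = 256, region_label = "region") {
  px <- as_pixel_matrix(img)
  if (!is.logical(region) || !identical(dim(region), dim(px)))
    stop("'region' must be a logical matrix matching the image", call. = FALSE)
  if (!any(region)) stop("empty region", call. = FALSE)
  v <- px[region]
  edges <- seq(0, 1, length.out = n_bins + 1)
  # right-closed bins except the first, as hist() does; values at 1 land in
  # the last bin
  bin <- pmin(pmax(ceiling(v * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 region_label = region_label,
                 mean = mean(v), sd = stats::sd(v)),
            class = "region_histogram")
}

#' Overlap coefficient of two region histograms
#'
#' \eqn{\sum_i \min(p_i, q_i)} over matched bins of the two normalized
#' histograms: 1 for identical normalized histograms, 0 for disjoint
#' support.  Quantifies how separable two intensity distributions are
#' (lower overlap = easier threshold/contour separation).
#'
#' @param h1,h2 `region_histogram` objects with identical bin edges.
#' @return a fraction in \[0, 1\].
#' @export
histogram_overlap <- function(h1, h2) {
  if (!inherits(h1, "region_histogram") || !inherits(h2, "region_histogram"))
    stop("arguments must be region_histogram objects", call. = FALSE)
  if (!isTRUE(all.equal(h1$bin_edges, h2$bin_edges)))
    stop("histograms have mismatched bin edges", call. = FALSE)
  p <- h1$counts / sum(h1$counts)
  q <- h2$counts / sum(h2$counts)
  sum(pmin(p, q))
}

# Analytic intersection of a horizontal/vertical pixel line with a rotated
# ellipse; returns the 0 or 2 coordinates along the line.
line_ellipse_intersections <- function(orientation, position, ellipse) {
  ct <- cos(ellipse$rot); st <- sin(ellipse$rot)
  a <- ellipse$a; b <- ellipse$b
  if (orientation == "horizontal") {
    v <- position - ellipse$cy
    A <- ct^2 / a^2 + st^2 / b^2
    B <- 2 * v * (ct * st / a^2 - st * ct / b^2)
    C <- v^2 * (st^2 / a^2 + ct^2 / b^2) - 1
    off <- ellipse$cx
  } else {
    u <- position - ellipse$cx
    A <- st^2 / a^2 + ct^2 / b^2
    B <- 2 * u * (ct * st / a^2 - st * ct / b^2)
    C <- u^2 * (ct^2 / a^2 + st^2 / b^2) - 1
    off <- ellipse$cy
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sort(off + (-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

#' Intensity profile along an image row or column
#'
#' Samples the full horizontal or vertical pixel line and marks where it
#' crosses a reference ellipse (the TM outline), computed analytically on
#' the continuous ellipse and rounded to pixel indices.  The profile makes
#' the boundary intensity step visible: a strong step at the marks indicates
#' channel contrast suitable for contour segmentation.
#'
#' @param img a [channel_image()] or numeric matrix.
#' @param orientation `"horizontal"` (fixed row) or `"vertical"` (fixed
#'   column).
#' @param position 1-based row/column index of the line.
#' @param reference_ellipse list with `cx`, `cy` (0-based pixel coordinates,
#'   x = column - 1, y = row - 1), `a`, `b` (semi-axes, px), `rot` (radians).
#' @return a `line_profile`: list with `coord` (0-based positions along the
#'   line), `intensity`, `boundary_marks` (0 or 2 coordinates), `missed`
#'   (TRUE with a warning when the line does not cross the ellipse),
#'   `orientation`, `position`.
#' @export
line_profile <- function(img, orientation = c("horizontal", "vertical"),
                         position, reference_ellipse) {
  orientation <- match.arg(orientation)
  px <- as_pixel_matrix(img)
  nmax <- if (orientation == "horizontal") nrow(px) else ncol(px)
  if (position < 1 || position > nmax) stop("'position' out of bounds", call. = FALSE)
  vals <- if (orientation == "horizontal") px[position, ] else px[, position]
  marks <- line_ellipse_intersections(orientation, position - 1, reference_ellipse)
  missed <- length(marks) == 0
  if (missed) warning("line does not intersect the reference ellipse")
  structure(list(coord = seq_along(vals) - 1, intensity = unname(vals),
                 boundary_marks = round(marks), missed = missed,
                 orientation = orientation, position = position),
            class = "line_profile")
}

#' Export a region histogram or line profile as CSV
#'
#' Histograms get columns `bin_left`, `bin_right`, `count`; profiles get
#' `index`, `intensity`.
#'
#' @param x a `region_histogram` or `line_profile`.
#' @param path destination CSV path.
#' @export
write_analysis_csv <- function(x, path) {
  if (inherits(x, "region_histogram")) {
    n <- length(x$counts)
    df <- data.frame(bin_left = x$bin_edges[seq_len(n)],
                     bin_right = x$bin_edges[seq_len(n) + 1],
                     count = x$counts)
  } else if (inherits(x, "line_profile")) {
    df <- data.frame(index = x$coord, intensity = x$intensity)
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
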