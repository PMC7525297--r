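#' Construct a phantom specification
#'
#' Geometric and per-channel photometric description of a synthetic
#' multispectral eardrum phantom: an elliptical tympanic membrane (TM) on a
#' homogeneous ear-canal wall background, a malleus-handle strip from the
#' upper ellipse boundary to the umbo (ellipse center), a cone-of-light
#' wedge in the anterior-inferior quadrant, and curvilinear blood vessels
#' whose visibility depends on the illumination channel.
#'
#' Coordinates are 0-based pixel coordinates with `x = column - 1` (right)
#' and `y = row - 1` (down); all intensities live on the \[0, 1\] scale.
#'
#' @param width,height raster size in pixels.
#' @param tm_ellipse list `cx, cy, a, b, rot`: center, semi-axes (px) and
#'   rotation (radians) of the TM ellipse; must lie strictly inside the
#'   image.
#' @param malleus_width width of the malleus-handle strip (px).
#' @param cone list `direction` (radians, image coordinates) and `extent`
#'   (radians) of the cone-of-light wedge rooted at the umbo.
#' @param n_vessels,vessel_width number and stroke width (px) of random
#'   smooth vessel curves.
#' @param blur_sigma Gaussian point-spread sigma (px) applied to the clean
#'   scene before noise, emulating endoscope optics.
#' @param photometry named list with entries `white`, `red`, `green`,
#'   `blue`; each a list `tm_mean, outside_mean, malleus_mean,
#'   vessel_contrast, cone_gain, noise_sd` (means and sd in \[0, 1\],
#'   `vessel_contrast >= 0`).
#' @return a validated `phantom_spec`.
#' @seealso [default_phantom_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(width, height, tm_ellipse, malleus_width, cone,
                         n_vessels, vessel_width, blur_sigma, photometry) {
  spec <- structure(list(width = width, height = height,
                         tm_ellipse = tm_ellipse,
                         malleus_width = malleus_width, cone = cone,
                         n_vessels = n_vessels, vessel_width = vessel_width,
                         blur_sigma = blur_sigma, photometry = photometry),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks every structural invariant and stops with a message naming the
#' first violated one.
#'
#' @param spec a `phantom_spec`.
#' @return `invisible(TRUE)` on success.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(msg) stop(sprintf("invalid phantom_spec: %s", msg), call. = FALSE)
  e <- spec$tm_ellipse
  for (nm in c("cx", "cy", "a", "b", "rot"))
    if (is.null(e[[nm]]) || !is.finite(e[[nm]])) fail(sprintf("tm_ellipse$%s missing", nm))
  if (e$a <= 0 || e$b <= 0) fail("ellipse semi-axes must be positive")
  # bounding half-extents of the rotated ellipse
  ex <- sqrt((e$a * cos(e$rot))^2 + (e$b * sin(e$rot))^2)
  ey <- sqrt((e$a * sin(e$rot))^2 + (e$b * cos(e$rot))^2)
  if (e$cx - ex <= 0 || e$cx + ex >= spec$width - 1 ||
      e$cy - ey <= 0 || e$cy + ey >= spec$height - 1)
    fail("tm_ellipse must lie strictly inside the image bounds")
  if (spec$malleus_width <= 0) fail("malleus_width must be positive")
  if (spec$n_vessels < 0) fail("n_vessels must be >= 0")
  if (spec$vessel_width <= 0) fail("vessel_width must be positive")
  if (spec$blur_sigma < 0) fail("blur_sigma must be >= 0")
  chans <- c("white", "red", "green", "blue")
  if (!all(chans %in% names(spec$photometry)))
    fail("photometry must cover white, red, green, blue")
  for (ch in chans) {
    p <- spec$photometry[[ch]]
    for (nm in c("tm_mean", "outside_mean", "malleus_mean", "noise_sd"))
      if (is.null(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
        fail(sprintf("%s$%s must lie in [0, 1]", ch, nm))
    if (is.null(p$vessel_contrast) || p$vessel_contrast < 0)
      fail(sprintf("%s$vessel_contrast must be >= 0", ch))
    if (is.null(p$cone_gain) || !is.finite(p$cone_gain))
      fail(sprintf("%s$cone_gain missing", ch))
  }
  invisible(TRUE)
}

#' Default phantom specification
#'
#' Encodes the channel contrast structure of multispectral otoendoscopy of a
#' healthy eardrum at the acquisition resolution of 976 x 494 px (about
#' 40 px/mm across the TM):
#' \itemize{
#'   \item red (630 nm): haemoglobin absorbs least, so vessels are invisible
#'     (`vessel_contrast = 0`) and the collagen-rich TM stands in strong
#'     contrast to the ear-canal wall, while the malleus handle takes the
#'     same intensity as the outside region; the outside region is
#'     homogeneous with the smallest noise.
#'   \item white and green: vessels are dark and the inside/outside mean
#'     intensities nearly coincide, so their histograms overlap.
#'   \item blue (450 nm): poorly illuminated — all means low — with the
#'     largest noise.
#' }
#'
#' @param scale multiplies every geometric quantity (use e.g. `0.25` for
#'   fast small-raster experiments); photometry is scale-free.
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(scale = 1) {
  s <- scale
  phantom_spec(
    width = round(976 * s), height = round(494 * s),
    tm_ellipse = list(cx = 500 * s, cy = 250 * s,
                      a = 230 * s, b = 165 * s, rot = 0.3),
    malleus_width = 36 * s,
    cone = list(direction = 1.9, extent = 0.5),
    n_vessels = 6, vessel_width = max(1.5, 3 * s),
    blur_sigma = max(0.6, 2 * s),
    photometry = list(
      white = list(tm_mean = 0.62, outside_mean = 0.55, malleus_mean = 0.45,
                   vessel_contrast = 0.18, cone_gain = 0.25, noise_sd = 0.040),
      red   = list(tm_mean = 0.78, outside_mean = 0.40, malleus_mean = 0.40,
                   vessel_contrast = 0.00, cone_gain = 0.12, noise_sd = 0.020),
      green = list(tm_mean = 0.50, outside_mean = 0.44, malleus_mean = 0.35,
                   vessel_contrast = 0.20, cone_gain = 0.22, noise_sd = 0.045),
      blue  = list(tm_mean = 0.22, outside_mean = 0.18, malleus_mean = 0.15,
                   vessel_contrast = 0.10, cone_gain = 0.10, noise_sd = 0.100)
    )
  )
}

# 0-based pixel-center coordinate grids for a spec-sized raster.
coord_grids <- function(spec) {
  nr <- spec$height; nc <- spec$width
  list(x = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
       y = matrix(rep(seq_len(nr) - 1, times = nc), nr, nc))
}

# Point-in-ellipse raster plus the rotated-frame coordinates (x along the
# a-axis, y along the b-axis, image-down positive).
ellipse_frame <- function(spec) {
  g <- coord_grids(spec)
  e <- spec$tm_ellipse
  dx <- g$x - e$cx; dy <- g$y - e$cy
  ct <- cos(e$rot); st <- sin(e$rot)
  xr <- dx * ct + dy * st
  yr <- -dx * st + dy * ct
  list(xr = xr, yr = yr, dx = dx, dy = dy,
       inside = (xr / e$a)^2 + (yr / e$b)^2 <= 1)
}

#' Rasterize an ellipse to a binary mask
#'
#' @param width,height raster size (px).
#' @param cx,cy,a,b,rot ellipse center (0-based pixel coordinates),
#'   semi-axes (px) and rotation (radians).
#' @return logical matrix, `TRUE` inside the ellipse.
#' @export
rasterize_ellipse <- function(width, height, cx, cy, a, b, rot = 0) {
  spec <- list(width = width, height = height,
               tm_ellipse = list(cx = cx, cy = cy, a = a, b = b, rot = rot))
  ellipse_frame(spec)$inside
}

phantom_masks <- function(spec) {
  f <- ellipse_frame(spec)
  tm <- f$inside
  malleus <- tm & abs(f$xr) <= spec$malleus_width / 2 & f$yr <= 0
  th <- atan2(f$dy, f$dx)
  dd <- atan2(sin(th - spec$cone$direction), cos(th - spec$cone$direction))
  cone <- tm & abs(dd) <= spec$cone$extent / 2
  list(tm = tm, malleus = malleus, cone = cone)
}

# Random smooth vessel curves (cubic Bezier strokes crossing the field of
# view), drawn with the current RNG stream.
draw_vessels <- function(spec) {
  nr <- spec$height; nc <- spec$width
  mask <- matrix(FALSE, nr, nc)
  if (spec$n_vessels < 1) return(mask)
  e <- spec$tm_ellipse
  R0 <- 1.35 * max(e$a, e$b)
  rw <- spec$vessel_width / 2
  ro <- ceiling(rw)
  off <- expand.grid(di = -ro:ro, dj = -ro:ro)
  off <- off[off$di^2 + off$dj^2 <= rw^2, , drop = FALSE]
  if (nrow(off) == 0) off <- data.frame(di = 0, dj = 0)
  for (v in seq_len(spec$n_vessels)) {
    th0 <- runif(1, 0, 2 * pi)
    th1 <- th0 + pi + runif(1, -0.7, 0.7)
    p0 <- c(e$cx + R0 * cos(th0), e$cy + R0 * sin(th0))
    p3 <- c(e$cx + R0 * cos(th1), e$cy + R0 * sin(th1))
    dirv <- (p3 - p0) / sqrt(sum((p3 - p0)^2))
    perp <- c(-dirv[2], dirv[1])
    p1 <- p0 + (p3 - p0) / 3 + perp * runif(1, -0.3, 0.3) * R0
    p2 <- p0 + 2 * (p3 - p0) / 3 + perp * runif(1, -0.3, 0.3) * R0
    t <- seq(0, 1, length.out = 400)
    bx <- (1 - t)^3 * p0[1] + 3 * (1 - t)^2 * t * p1[1] +
          3 * (1 - t) * t^2 * p2[1] + t^3 * p3[1]
    by <- (1 - t)^3 * p0[2] + 3 * (1 - t)^2 * t * p1[2] +
          3 * (1 - t) * t^2 * p2[2] + t^3 * p3[2]
    cc <- round(bx) + 1L; rr <- round(by) + 1L
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[keep]; cc <- cc[keep]
    if (length(rr) == 0) next
    for (k in seq_len(nrow(off))) {
      r2 <- rr + off$di[k]; c2 <- cc + off$dj[k]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      mask[cbind(r2[ok], c2[ok])] <- TRUE
    }
  }
  mask
}

#' Generate one synthetic multispectral eardrum set
#'
#' Renders the four illumination channels described by `spec`: the outside
#' (ear-canal wall) region at `outside_mean`, the TM ellipse at `tm_mean`,
#' the malleus strip at `malleus_mean`, the cone-of-light wedge brightened
#' by `cone_gain`, and vessels darkened by `vessel_contrast`; the clean
#' scene is blurred by the optics PSF, then independent Gaussian noise with
#' per-channel `noise_sd` is added and the result clipped to \[0, 1\].
#' Fully deterministic given `(spec, seed)`; ground-truth masks depend only
#' on geometry, never on photometric parameters.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for vessel geometry and noise.
#' @return a `multispectral_set`: list with `channels` (named list of
#'   [channel_image()] for `white`, `red`, `green`, `blue`), `gt_tm_mask`
#'   (TM ellipse plus malleus strip), `gt_malleus_mask`, `gt_vessel_mask`,
#'   `seed`, and the `spec` used.
#' @export
generate_phantom <- function(spec, seed) {
  validate_phantom_spec(spec)
  masks <- phantom_masks(spec)
  with_local_seed(seed, {
    vessels <- draw_vessels(spec)
    channels <- list()
    for (ch in c("white", "red", "green", "blue")) {
      p <- spec$photometry[[ch]]
      img <- matrix(p$outside_mean, spec$height, spec$width)
      img[masks$tm] <- p$tm_mean
      img[masks$malleus] <- p$malleus_mean
      img[masks$cone] <- img[masks$cone] + p$cone_gain
      img[vessels] <- img[vessels] - p$vessel_contrast
      if (spec$blur_sigma > 0)
        img <- EBImage::imageData(EBImage::gblur(img, sigma = spec$blur_sigma))
      img <- img + matrix(rnorm(length(img), sd = p$noise_sd),
                          nrow(img), ncol(img))
      channels[[ch]] <- channel_image(clamp01(img), ch)
    }
    structure(list(channels = channels,
                   gt_tm_mask = masks$tm | masks$malleus,
                   gt_malleus_mask = masks$malleus,
                   gt_vessel_mask = vessels,
                   seed = seed, spec = spec),
              class = "multispectral_set")
  })
}

#' @export
print.multispectral_set <- function(x, ...) {
  cat(sprintf("<multispectral_set> %d x %d, channels: %s, seed %d\n",
              x$spec$height, x$spec$width,
              paste(names(x$channels), collapse = "/"), x$seed))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Produces `n` phantom sets with distinct seeds and geometry jittered by up
#' to ±5% on each ellipse parameter, emulating anatomical variation across
#' subjects.  Fully reproducible from `master_seed`; each returned set
#' carries its own jittered spec and derived seed, so
#' `generate_phantom(set$spec, set$seed)` regenerates it exactly.
#'
#' @param spec base [phantom_spec()].
#' @param n number of sets (>= 1).
#' @param master_seed integer seed controlling jitter and derived seeds.
#' @param jitter relative jitter bound on each ellipse parameter.
#' @return list of `multispectral_set`.
#' @export
generate_cohort <- function(spec, n, master_seed, jitter = 0.05) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  validate_phantom_spec(spec)
  with_local_seed(master_seed, {
    lapply(seq_len(n), function(i) {
      jf <- runif(5, 1 - jitter, 1 + jitter)
      seed_i <- sample.int(.Machine$integer.max - 1L, 1)
      jspec <- spec
      e <- spec$tm_ellipse
      jspec$tm_ellipse <- list(cx = e$cx * jf[1], cy = e$cy * jf[2],
                               a = e$a * jf[3], b = e$b * jf[4],
                               rot = e$rot * jf[5])
      validate_phantom_spec(jspec)
      generate_phantom(jspec, seed_i)
    })
  })
}

#' Write a multispectral set to disk
#'
#' Each channel goes to a grayscale PNG, masks to 0/255 PNGs, and a sidecar
#' JSON records the spec, seed, and file manifest.
#'
#' @param set a `multispectral_set`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @export
write_multispectral_set <- function(set, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  for (ch in names(set$channels)) {
    f <- file.path(dir, sprintf("%s_%s.png", prefix, ch))
    write_image(set$channels[[ch]], f)
    manifest[[ch]] <- basename(f)
  }
  for (mk in c("gt_tm_mask", "gt_malleus_mask", "gt_vessel_mask")) {
    f <- file.path(dir, sprintf("%s_%s.png", prefix, mk))
    write_image(set[[mk]], f)
    manifest[[mk]] <- basename(f)
  }
  side <- file.path(dir, sprintf("%s_manifest.json", prefix))
  jsonlite::write_json(list(seed = set$seed, spec = unclass(set$spec),
                            files = manifest),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' Read/write a phantom spec as YAML
#'
#' @param spec a `phantom_spec`.
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(x$width, x$height, x$tm_ellipse, x$malleus_width, x$cone,
               x$n_vessels, x$vessel_width, x$blur_sigma, x$photometry)
}
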