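#' Smoothed Heaviside band function
#'
#' Band-limited indicator of the contour interior.  The contour is the zero
#' level set of a signed distance field `phi` that is negative inside, so the
#' function equals 1 for `phi <= -epsilon`, 0 for `phi >= epsilon`, and the
#' smooth interpolant
#' \deqn{\tfrac12\left(1 - \phi/\varepsilon -
#'   \tfrac1\pi \sin(\pi\phi/\varepsilon)\right)}
#' in between.  It is continuous and monotone non-increasing, and its
#' derivative magnitude is [smoothed_dirac()].
#'
#' @param phi numeric vector/matrix of signed-distance values (pixels;
#'   negative inside the contour).
#' @param epsilon positive band half-width (pixels).
#' @return values in \[0, 1\], same shape as `phi`.
#' @seealso [smoothed_dirac()]
#' @export
smoothed_heaviside <- function(phi, epsilon) {
  stopifnot_scalar(epsilon, "epsilon")
  if (epsilon <= 0) stop("'epsilon' must be > 0", call. = FALSE)
  out <- 0.5 * (1 - phi / epsilon - sin(pi * phi / epsilon) / pi)
  out[phi <= -epsilon] <- 1
  out[phi >= epsilon] <- 0
  out
}

#' Smoothed Dirac band function
#'
#' Derivative magnitude of [smoothed_heaviside()]: zero for
#' `|phi| >= epsilon` and \eqn{(1 + \cos(\pi\phi/\varepsilon))/2\varepsilon}
#' inside the band.  Selects the narrow band of pixels around the contour
#' where the level-set update acts; integrates to 1 over the band.
#'
#' @inheritParams smoothed_heaviside
#' @return non-negative values, same shape as `phi`.
#' @export
smoothed_dirac <- function(phi, epsilon) {
  stopifnot_scalar(epsilon, "epsilon")
  if (epsilon <= 0) stop("'epsilon' must be > 0", call. = FALSE)
  out <- (1 + cos(pi * phi / epsilon)) / (2 * epsilon)
  out[abs(phi) >= epsilon] <- 0
  out
}

#' Signed distance field from a binary mask
#'
#' Exact Euclidean signed distance on pixel centers: the value at each pixel
#' is (distance to the nearest interior pixel) minus (distance to the nearest
#' exterior pixel), so the interior of the mask is negative and the zero
#' level set traces the mask boundary.
#'
#' @param mask logical matrix with at least one `TRUE` and one `FALSE` pixel.
#' @param epsilon band half-width stored with the field (pixels).
#' @return a `level_set_field`: list with `phi` (numeric matrix) and
#'   `epsilon`.
#' @export
sdf_from_mask <- function(mask, epsilon = 1.5) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("mask has no interior pixels", call. = FALSE)
  if (all(mask)) stop("mask has no exterior pixels", call. = FALSE)
  d_to_in <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask)))
  d_to_ex <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  structure(list(phi = d_to_in - d_to_ex, epsilon = epsilon),
            class = "level_set_field")
}

#' Local interior/exterior means around a point
#'
#' Means of the image over the disc of `local_radius` around `point`,
#' split into the contour interior (`phi < 0`) and exterior using smoothed
#' Heaviside weights.  This is the localized statistic that drives the
#' active-contour force: each contour point sees only its own neighbourhood
#' rather than global region means.
#'
#' @param img a [channel_image()] or numeric matrix.
#' @param field a `level_set_field` from [sdf_from_mask()].
#' @param point integer `c(row, col)`, 1-based, inside the image.
#' @param local_radius disc radius in pixels (> 0).
#' @return list with `interior_mean`, `exterior_mean`, and logical flags
#'   `interior_empty` / `exterior_empty` (an empty side yields `NA` mean and
#'   a raised flag rather than `NaN`).
#' @export
local_means <- function(img, field, point, local_radius) {
  px <- as_pixel_matrix(img)
  phi <- field$phi
  stopifnot(identical(dim(px), dim(phi)))
  if (local_radius <= 0) stop("'local_radius' must be > 0", call. = FALSE)
  i0 <- point[1]; j0 <- point[2]
  if (i0 < 1 || i0 > nrow(px) || j0 < 1 || j0 > ncol(px))
    stop("'point' out of bounds", call. = FALSE)
  r <- ceiling(local_radius)
  ii <- max(1, i0 - r):min(nrow(px), i0 + r)
  jj <- max(1, j0 - r):min(ncol(px), j0 + r)
  di <- outer(ii - i0, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - j0)
  disc <- di^2 + dj^2 <= local_radius^2
  w_in <- smoothed_heaviside(phi[ii, jj, drop = FALSE], field$epsilon) * disc
  w_ex <- (1 - smoothed_heaviside(phi[ii, jj, drop = FALSE], field$epsilon)) * disc
  v <- px[ii, jj, drop = FALSE]
  s_in <- sum(w_in); s_ex <- sum(w_ex)
  list(
    interior_mean  = if (s_in > 1e-8) sum(w_in * v) / s_in else NA_real_,
    exterior_mean  = if (s_ex > 1e-8) sum(w_ex * v) / s_ex else NA_real_,
    interior_empty = s_in <= 1e-8,
    exterior_empty = s_ex <= 1e-8
  )
}

#' Parameters of the localized active contour
#'
#' @param epsilon band half-width of the smoothed Heaviside/Dirac pair
#'   (pixels).
#' @param local_radius radius of the disc over which local interior/exterior
#'   means are computed (pixels).  `default_contour_params()` scales the
#'   full-resolution default of 15 px proportionally to image size.
#' @param curvature_weight weight of the curvature (contour length)
#'   regularizer relative to the normalized data force.
#' @param step_size CFL-style cap: each iteration the maximal level-set
#'   update is `step_size` pixels.
#' @param max_iters iteration budget.
#' @param reinit_every rebuild `phi` as an exact signed distance field every
#'   this many iterations (a single Sussman relaxation sweep additionally
#'   runs every iteration to keep the band well-formed).
#' @param convergence_tol stop when the fraction of pixels changing label
#'   over a 10-iteration window drops below this.
#' @return a validated `contour_params` list.
#' @export
contour_params <- function(epsilon = 1.5, local_radius = 15,
                           curvature_weight = 0.2, step_size = 0.45,
                           max_iters = 600, reinit_every = 25,
                           convergence_tol = 1e-5) {
  p <- list(epsilon = epsilon, local_radius = local_radius,
            curvature_weight = curvature_weight, step_size = step_size,
            max_iters = max_iters, reinit_every = reinit_every,
            convergence_tol = convergence_tol)
  for (nm in names(p)) {
    stopifnot_scalar(p[[nm]], nm)
    if (p[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  if (convergence_tol >= 1) stop("'convergence_tol' must be in (0, 1)", call. = FALSE)
  structure(p, class = "contour_params")
}

#' Default contour parameters for a given image size
#'
#' The localization radius defaults to 15 px at the full acquisition
#' resolution (shorter side 494 px) and scales proportionally for smaller
#' rasters, with a floor of 8 px: the local interior/exterior statistics
#' only exert force within this radius, so it must stay comparable to the
#' worst-case distance between the initial contour and the true boundary.
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param ... overrides passed to [contour_params()].
#' @export
default_contour_params <- function(dim = c(494, 976), ...) {
  r <- max(8, round(15 * min(dim) / 494))
  args <- list(...)
  if (is.null(args$local_radius)) args$local_radius <- r
  do.call(contour_params, args)
}

#' Localized region-based active contour evolution
#'
#' Evolves the zero level set of a signed distance field from `init` under
#' the localized uniform-modelling (mean-separation) force: pixels inside the
#' narrow band move toward whichever side — local interior or local exterior
#' mean over the `(2 local_radius + 1)`-pixel square window — better
#' explains their intensity, plus a curvature regularizer.  (The evolution
#' uses a square window so the local means cost O(1) per pixel via
#' summed-area tables; [local_means()] offers the disc variant for
#' analysis.)  The data force is normalized to unit maximum per
#' iteration and the step obeys a CFL-style cap, the standard explicit
#' scheme for this energy.  Deterministic: no randomness anywhere.
#'
#' @param img a [channel_image()] or numeric matrix with values in \[0, 1\].
#' @param init logical matrix, the initial interior (both phases must be
#'   present).
#' @param params a [contour_params()] object.
#' @return a `segmentation_result`: list with `mask` (logical, `phi < 0`),
#'   `iterations_run`, `converged`, `energy_trace`, and the final `phi`.
#' @export
evolve_contour <- function(img, init, params = default_contour_params(dim(as_pixel_matrix(img)))) {
  px <- as_pixel_matrix(img)
  if (!is.logical(init) || !identical(dim(init), dim(px)))
    stop("'init' must be a logical matrix matching the image", call. = FALSE)
  if (!inherits(params, "contour_params")) stop("invalid 'params'", call. = FALSE)
  field <- sdf_from_mask(init, epsilon = params$epsilon)
  phi <- field$phi
  npix <- length(phi)
  changes <- integer(0)
  energy <- numeric(0)
  mask_prev <- init
  converged <- FALSE
  it <- 0
  while (it < params$max_iters) {
    it <- it + 1
    fb <- ac_force_band(px, phi, params$epsilon, as.integer(params$local_radius))
    if (length(fb$idx) == 0L)
      stop(sprintf("contour vanished at iteration %d", it), call. = FALSE)
    f <- fb$force / (max(abs(fb$force)) + 1e-12)
    kap <- curvature_at(phi, fb$idx)
    dphi <- f + params$curvature_weight * kap
    dt <- params$step_size / (max(abs(dphi)) + 1e-12)
    phi[fb$idx] <- phi[fb$idx] + dt * dphi
    phi <- sussman_step(phi, 0.5)
    if (it %% params$reinit_every == 0) {
      m <- phi < 0
      if (!any(m)) stop(sprintf("contour vanished at iteration %d", it), call. = FALSE)
      if (all(m)) stop(sprintf("contour filled the image at iteration %d", it), call. = FALSE)
      phi <- sdf_from_mask(m, epsilon = params$epsilon)$phi
    }
    mask_now <- phi < 0
    changes <- c(changes, sum(mask_now != mask_prev))
    energy <- c(energy, fb$energy)
    mask_prev <- mask_now
    if (it >= 10 && sum(utils::tail(changes, 10)) / npix < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  mask <- phi < 0
  if (!any(mask)) stop(sprintf("contour vanished at iteration %d", it), call. = FALSE)
  structure(list(mask = mask, iterations_run = it, converged = converged,
                 energy_trace = energy, phi = phi),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d, %d interior px, %d iterations (%s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$iterations_run,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Coarse-to-fine localized active contour
#'
#' Runs [evolve_contour()] on a downscaled copy of the image first, then
#' refines at full resolution from the upsampled coarse result.  At the
#' coarse level both the initial-contour offset and the localization radius
#' shrink by the same factor, but downsampling also averages away noise, so
#' the weak long-range force that pulls the contour across homogeneous
#' terrain — swamped by noise at full resolution — becomes effective and
#' the contour locks onto the boundary even when the initial ellipse sits
#' further away than `local_radius` (the classic failure mode of localized
#' energies).  The full-resolution stage then only refines by a few
#' pixels.  The coarse radius scales proportionally, which also keeps the
#' local window narrower than elongated structures (e.g. the malleus
#' handle) at every level, so the contour cannot tunnel along them.
#' Deterministic.
#'
#' @inheritParams evolve_contour
#' @param coarse_scale downscaling factor of the first stage (default 0.25);
#'   use `NULL` or 1 to skip straight to single-scale evolution.
#' @return a `segmentation_result` from the full-resolution stage, with the
#'   coarse stage's iteration count and energy trace attached as
#'   `iterations_coarse` / `energy_trace_coarse`.
#' @export
evolve_contour_pyramid <- function(img, init,
                                   params = default_contour_params(dim(as_pixel_matrix(img))),
                                   coarse_scale = 0.25) {
  px <- as_pixel_matrix(img)
  if (is.null(coarse_scale) || coarse_scale >= 1 ||
      round(min(dim(px)) * coarse_scale) < 32)
    return(evolve_contour(px, init, params))
  nr <- round(nrow(px) * coarse_scale); nc <- round(ncol(px) * coarse_scale)
  small_img <- EBImage::imageData(EBImage::resize(px, w = nr, h = nc))
  small_init <- EBImage::imageData(EBImage::resize(init * 1, w = nr, h = nc)) > 0.5
  cp <- params
  cp$local_radius <- max(2, round(params$local_radius * coarse_scale))
  coarse <- evolve_contour(small_img, small_init, cp)
  up <- EBImage::imageData(EBImage::resize(coarse$mask * 1, w = nrow(px), h = ncol(px))) > 0.5
  if (!any(up) || all(up)) up <- init  # degenerate upsample: fall back
  fine <- evolve_contour(px, up, params)
  fine$iterations_coarse <- coarse$iterations_run
  fine$energy_trace_coarse <- coarse$energy_trace
  fine
}

#' Boundary pixels of a binary mask
#'
#' Mask pixels with at least one 4-neighbour outside the mask (pixels on the
#' image edge count their out-of-image neighbours as exterior).
#'
#' @param mask non-empty logical matrix.
#' @return integer matrix with columns `row`, `col` (1-based).
#' @export
mask_boundary <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask has no boundary", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb_all <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
            pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  b <- core & !nb_all
  out <- which(b, arr.ind = TRUE)
  colnames(out) <- c("row", "col")
  out
}
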