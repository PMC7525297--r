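test_that("smoothed Heaviside matches its piecewise limits and midpoint", {
  for (eps in c(0.5, 1, 1.5, 3)) {
    expect_equal(smoothed_heaviside(-2 * eps, eps), 1)
    expect_equal(smoothed_heaviside(-eps, eps), 1)
    expect_equal(smoothed_heaviside(0, eps), 0.5)
    expect_equal(smoothed_heaviside(eps, eps), 0)
    expect_equal(smoothed_heaviside(2 * eps, eps), 0)
  }
  # direct evaluation of the smooth branch at phi = -eps/2, eps = 1
  expect_equal(smoothed_heaviside(-0.5, 1),
               0.5 * (1 + 0.5 + sin(pi / 2) / pi))
  # continuity and monotonicity across the band
  x <- seq(-2, 2, by = 1e-3)
  h <- smoothed_heaviside(x, 1.5)
  expect_true(all(diff(h) <= 1e-12))
  expect_true(max(abs(diff(h))) < 2e-3)  # no jumps
  expect_true(all(h >= 0 & h <= 1))
  expect_error(smoothed_heaviside(0, 0), "epsilon")
})

test_that("smoothed Dirac is the Heaviside derivative and integrates to one", {
  for (eps in c(0.7, 1.5)) {
    expect_equal(smoothed_dirac(2 * eps, eps), 0)
    expect_equal(smoothed_dirac(-2 * eps, eps), 0)
    expect_equal(smoothed_dirac(eps, eps), 0)
    expect_equal(smoothed_dirac(-eps, eps), 0)
    expect_equal(smoothed_dirac(0, eps), 1 / eps)
    # numerical quadrature over the band
    x <- seq(-eps, eps, length.out = 20001)
    integral <- sum(smoothed_dirac(x, eps)) * (x[2] - x[1])
    expect_equal(integral, 1, tolerance = 1e-6)
  }
  # finite-difference agreement with the Heaviside slope
  h <- 1e-5
  for (phi in seq(-1.4, 1.4, by = 0.2)) {
    fd <- abs(smoothed_heaviside(phi + h, 1.5) - smoothed_heaviside(phi - h, 1.5)) / (2 * h)
    expect_equal(smoothed_dirac(phi, 1.5), fd, tolerance = 1e-4)
  }
})

test_that("signed distance from mask matches the all-pairs oracle", {
  # 3x3 single interior center pixel
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  phi <- sdf_from_mask(m)$phi
  expect_equal(phi[2, 2], -1)
  expect_equal(phi[1, 2], 1)
  expect_equal(phi[2, 1], 1)
  expect_equal(phi[1, 1], sqrt(2))
  # random masks vs oracle; sign matches mask everywhere
  set.seed(11)
  for (k in 1:20) {
    m <- random_mask(8, 8)
    phi <- sdf_from_mask(m)$phi
    expect_equal(phi, brute_sdf(m))
    expect_true(all((phi < 0) == m))
    # complement is the negation up to the discrete half-pixel asymmetry
    expect_lt(max(abs(sdf_from_mask(!m)$phi + phi)), 1 + 1e-9)
  }
  expect_error(sdf_from_mask(matrix(TRUE, 3, 3)), "exterior")
  expect_error(sdf_from_mask(matrix(FALSE, 3, 3)), "interior")
})

test_that("local means split a two-phase patch at the zero level", {
  # constant image: both means equal the constant
  m <- matrix(FALSE, 11, 11); m[, 1:5] <- TRUE
  f <- sdf_from_mask(m)
  lm <- local_means(matrix(0.7, 11, 11), f, c(6, 5), 3)
  expect_equal(lm$interior_mean, 0.7)
  expect_equal(lm$exterior_mean, 0.7)
  # two-phase image split by the zero level set
  img <- matrix(0.9, 11, 11); img[, 1:5] <- 0.1
  lm <- local_means(img, f, c(6, 5), 3)
  # band blur mixes a little of the other phase into each side
  expect_equal(lm$interior_mean, 0.1, tolerance = 0.12)
  expect_equal(lm$exterior_mean, 0.9, tolerance = 0.12)
  # direct weighted-mean oracle at the same point
  w <- matrix(0, 11, 11)
  for (i in 1:11) for (j in 1:11)
    if ((i - 6)^2 + (j - 5)^2 <= 9)
      w[i, j] <- smoothed_heaviside(f$phi[i, j], f$epsilon)
  sel <- matrix(0, 11, 11)
  for (i in 1:11) for (j in 1:11) sel[i, j] <- (i - 6)^2 + (j - 5)^2 <= 9
  expect_equal(lm$interior_mean, sum(w * img) / sum(w))
  expect_equal(lm$exterior_mean,
               sum((sel - w) * img) / sum(sel - w))
  # ball entirely on one side: the other side is flagged, not NaN
  lm2 <- local_means(img, f, c(6, 2), 2)
  expect_true(lm2$exterior_empty)
  expect_true(is.na(lm2$exterior_mean))
  expect_false(lm2$interior_empty)
})

test_that("mask boundary agrees with the brute-force neighbour check", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  b <- mask_boundary(m)
  expect_equal(nrow(b), 8)  # perimeter of the 3x3 block
  expect_false(any(b[, 1] == 3 & b[, 2] == 3))
  # single pixel is its own boundary
  s <- matrix(FALSE, 4, 4); s[2, 3] <- TRUE
  expect_equal(unname(mask_boundary(s)), matrix(c(2, 3), 1))
  # one-pixel-thick ring: boundary of boundary = boundary
  ring <- matrix(FALSE, 7, 7); ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  rb <- mask_boundary(ring)
  rb_mask <- matrix(FALSE, 7, 7); rb_mask[rb] <- TRUE
  expect_equal(rb_mask, ring)
  set.seed(21)
  for (k in 1:10) {
    m <- random_mask(7, 7)
    got <- mask_boundary(m)
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 brute_boundary(m))
  }
  expect_error(mask_boundary(matrix(FALSE, 3, 3)), "empty")
})

test_that("contour recovers noiseless two-phase discs and ellipses", {
  set.seed(5)
  for (k in 1:10) {
    cx <- runif(1, 40, 60); cy <- runif(1, 40, 60)
    a <- runif(1, 16, 24); b <- runif(1, 16, 24); rot <- runif(1, 0, pi)
    truth <- rasterize_ellipse(100, 100, cx, cy, a, b, rot)
    img <- matrix(0.2, 100, 100); img[truth] <- 0.8
    init <- rasterize_ellipse(100, 100, cx + runif(1, -4, 4),
                              cy + runif(1, -4, 4),
                              a * 1.15, b * 1.15, rot)
    res <- evolve_contour(img, init, default_contour_params(c(100, 100)))
    expect_gte(dice(res$mask, truth), 0.99)
  }
})

test_that("contour evolution is a near-fixed point at the true region", {
  truth <- rasterize_ellipse(80, 80, 40, 38, 20, 16, 0.4)
  img <- matrix(0.25, 80, 80); img[truth] <- 0.75
  res <- evolve_contour(img, truth, default_contour_params(c(80, 80)))
  expect_gte(dice(res$mask, truth), 0.99)
})

test_that("constant image: curvature-only motion never grows the region", {
  img <- matrix(0.5, 60, 60)
  init <- rasterize_ellipse(60, 60, 30, 30, 15, 10, 0)
  p <- default_contour_params(c(60, 60), max_iters = 80)
  res <- evolve_contour(img, init, p)
  expect_lte(sum(res$mask), sum(init))
  expect_s3_class(res, "segmentation_result")
})

test_that("contour evolution is deterministic", {
  truth <- rasterize_ellipse(60, 60, 30, 30, 14, 14, 0)
  img <- matrix(0.3, 60, 60); img[truth] <- 0.7
  init <- rasterize_ellipse(60, 60, 28, 32, 18, 17, 0)
  r1 <- evolve_contour(img, init, default_contour_params(c(60, 60)))
  r2 <- evolve_contour(img, init, default_contour_params(c(60, 60)))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("contour parameter validation rejects bad values", {
  expect_error(contour_params(epsilon = -1), "epsilon")
  expect_error(contour_params(convergence_tol = 2), "convergence_tol")
  expect_error(evolve_contour(matrix(0.5, 5, 5), matrix(TRUE, 4, 4)), "init")
})
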