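test_that("default spec satisfies its channel-contrast invariants", {
  spec <- default_phantom_spec()
  expect_silent(validate_phantom_spec(spec))
  p <- spec$photometry
  # vessels invisible under red; malleus matches the ear-canal wall in red
  expect_equal(p$red$vessel_contrast, 0)
  expect_equal(p$red$malleus_mean, p$red$outside_mean)
  # inside/outside contrast: large in red, small in white and green
  gap <- sapply(p, function(q) abs(q$tm_mean - q$outside_mean))
  expect_gt(gap[["red"]], 3 * max(gap[["white"]], gap[["green"]]))
  # blue: dimmest illumination, noisiest channel
  expect_equal(max(sapply(p, function(q) q$noise_sd)), p$blue$noise_sd)
  expect_true(all(unlist(p$blue[c("tm_mean", "outside_mean", "malleus_mean")]) <
                  sapply(p[c("white", "red", "green")], function(q) q$tm_mean)))
})

test_that("spec validation names the violated invariant", {
  spec <- default_phantom_spec()
  bad <- spec; bad$tm_ellipse$cx <- 30
  expect_error(validate_phantom_spec(bad), "inside the image")
  bad <- spec; bad$photometry$green$tm_mean <- 1.4
  expect_error(validate_phantom_spec(bad), "tm_mean")
  bad <- spec; bad$photometry$white$vessel_contrast <- -0.1
  expect_error(validate_phantom_spec(bad), "vessel_contrast")
})

test_that("phantom generation is deterministic and well-formed", {
  spec <- test_spec()
  s1 <- generate_phantom(spec, 7)
  s2 <- generate_phantom(spec, 7)
  expect_identical(s1$channels$red$pixels, s2$channels$red$pixels)
  expect_identical(s1$gt_vessel_mask, s2$gt_vessel_mask)
  s3 <- generate_phantom(spec, 8)
  expect_false(identical(s1$channels$red$pixels, s3$channels$red$pixels))
  for (ch in names(s1$channels)) {
    px <- s1$channels[[ch]]$pixels
    expect_equal(dim(px), c(spec$height, spec$width))
    expect_true(all(px >= 0 & px <= 1))
  }
  # ground truth is photometry-invariant and a single connected component
  spec2 <- spec; spec2$photometry$red$tm_mean <- 0.5
  expect_identical(generate_phantom(spec2, 7)$gt_tm_mask, s1$gt_tm_mask)
  lab <- EBImage::bwlabel(EBImage::Image(s1$gt_tm_mask * 1))
  expect_equal(max(lab), 1)
})

test_that("ground-truth mask equals the brute-force ellipse-plus-strip raster", {
  spec <- default_phantom_spec(scale = 0.1)  # 98 x 49: cheap full scan
  set <- generate_phantom(spec, 3)
  e <- spec$tm_ellipse
  ell <- brute_ellipse_mask(spec$width, spec$height, e$cx, e$cy, e$a, e$b, e$rot)
  strip <- matrix(FALSE, spec$height, spec$width)
  for (i in seq_len(spec$height)) for (j in seq_len(spec$width)) {
    dx <- (j - 1) - e$cx; dy <- (i - 1) - e$cy
    xr <- dx * cos(e$rot) + dy * sin(e$rot)
    yr <- -dx * sin(e$rot) + dy * cos(e$rot)
    strip[i, j] <- ell[i, j] && abs(xr) <= spec$malleus_width / 2 && yr <= 0
  }
  expect_identical(set$gt_tm_mask, ell | strip)
  expect_identical(set$gt_malleus_mask, strip)
})

test_that("vessels leave no signal in the red channel", {
  spec <- test_spec()
  set <- generate_phantom(spec, 13)
  # re-render with all vessel contrast zeroed: red channel must be identical
  spec0 <- spec
  for (ch in names(spec0$photometry)) spec0$photometry[[ch]]$vessel_contrast <- 0
  set0 <- generate_phantom(spec0, 13)
  expect_identical(set$channels$red$pixels, set0$channels$red$pixels)
  # ... while white shows the vessels clearly
  v <- set$gt_vessel_mask
  expect_gt(mean(abs(set$channels$white$pixels[v] - set0$channels$white$pixels[v])),
            3 * spec$photometry$white$noise_sd / sqrt(sum(v)))
})

test_that("cohorts are reproducible, jittered, and regenerable per set", {
  spec <- test_spec()
  c1 <- generate_cohort(spec, 5, 42)
  c2 <- generate_cohort(spec, 5, 42)
  expect_equal(length(c1), 5)
  for (i in 1:5) {
    expect_identical(c1[[i]]$channels$blue$pixels, c2[[i]]$channels$blue$pixels)
    expect_equal(dim(c1[[i]]$channels$white$pixels),
                 c(spec$height, spec$width))
    # each set regenerates from its stored (spec, seed)
    expect_identical(generate_phantom(c1[[i]]$spec, c1[[i]]$seed)$gt_tm_mask,
                     c1[[i]]$gt_tm_mask)
  }
  # geometry actually jitters between sets
  expect_false(identical(c1[[1]]$spec$tm_ellipse, c1[[2]]$spec$tm_ellipse))
  # jitter stays within 5%
  for (i in 1:5) {
    ji <- unlist(c1[[i]]$spec$tm_ellipse) / unlist(spec$tm_ellipse)
    expect_true(all(ji >= 0.95 & ji <= 1.05))
  }
  expect_error(generate_cohort(spec, 0, 1), "n")
})

test_that("red channel separates inside from outside better than any other", {
  spec <- test_spec()
  for (seed in c(2, 12, 77)) {
    set <- generate_phantom(spec, seed)
    inside <- set$gt_tm_mask
    outside <- !inside
    ov <- sapply(names(set$channels), function(ch) {
      histogram_overlap(region_histogram(set$channels[[ch]], inside),
                        region_histogram(set$channels[[ch]], outside))
    })
    expect_true(all(ov[["red"]] < ov[c("white", "green", "blue")]))
    # outside-TM red histogram is the narrow homogeneous peak
    sd_out <- sapply(set$channels, function(im) sd(im$pixels[outside]))
    expect_lt(sd_out[["red"]], sd_out[["white"]])
  }
})

test_that("a multispectral set round-trips through disk", {
  spec <- default_phantom_spec(scale = 0.1)
  set <- generate_phantom(spec, 5)
  dir <- withr::local_tempdir()
  write_multispectral_set(set, dir)
  red <- read_image(file.path(dir, "phantom_red.png"), "red")
  expect_equal(red$pixels, set$channels$red$pixels, tolerance = 1 / 255)
  man <- jsonlite::read_json(file.path(dir, "phantom_manifest.json"))
  expect_equal(man$seed, 5)
  gt <- read_image(file.path(dir, "phantom_gt_tm_mask.png"))
  expect_identical(gt$pixels > 0.5, set$gt_tm_mask)
})
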