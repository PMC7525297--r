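# Independent brute-force oracles used to pin down expected values.

# All-pairs signed distance: (distance to nearest interior pixel) minus
# (distance to nearest exterior pixel), on pixel centers.
brute_sdf <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ins <- which(mask, arr.ind = TRUE)
  outs <- which(!mask, arr.ind = TRUE)
  phi <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d_in <- sqrt(min((ins[, 1] - i)^2 + (ins[, 2] - j)^2))
    d_out <- sqrt(min((outs[, 1] - i)^2 + (outs[, 2] - j)^2))
    phi[i, j] <- d_in - d_out
  }
  phi
}

# All-pairs directed Hausdorff on n x 2 point matrices.
brute_directed_hd <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    d <- sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2))
    worst <- max(worst, d)
  }
  worst
}

brute_max_hd <- function(A, B) max(brute_directed_hd(A, B), brute_directed_hd(B, A))

# Boundary by explicit 4-neighbour check (out-of-image counts as exterior).
brute_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
            if (i < nr) mask[i + 1, j] else FALSE,
            if (j > 1) mask[i, j - 1] else FALSE,
            if (j < nc) mask[i, j + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

# Pointwise rasterization of a rotated ellipse over every pixel center.
brute_ellipse_mask <- function(width, height, cx, cy, a, b, rot) {
  m <- matrix(FALSE, height, width)
  for (i in seq_len(height)) for (j in seq_len(width)) {
    dx <- (j - 1) - cx; dy <- (i - 1) - cy
    xr <- dx * cos(rot) + dy * sin(rot)
    yr <- -dx * sin(rot) + dy * cos(rot)
    m[i, j] <- (xr / a)^2 + (yr / b)^2 <= 1
  }
  m
}

# Random blob mask with both phases, for property tests.
random_mask <- function(nr, nc, p = 0.4) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  if (all(m)) m[sample(length(m), 1)] <- FALSE
  m
}

# Small phantom spec used throughout the unit tests (fast to render).
test_spec <- function() default_phantom_spec(scale = 0.25)
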