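#' Dice similarity coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} between two binary masks: 1 for identical
#' non-empty masks, 0 for disjoint ones.  Symmetric.
#'
#' @param A,B logical matrices of identical dimensions, not both empty.
#' @return a fraction in \[0, 1\].
#' @export
dice <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("mask dimensions differ", call. = FALSE)
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(A & B) / (nA + nB)
}

as_point_matrix <- function(A, name) {
  if (is.matrix(A) && is.numeric(A) && ncol(A) == 2) return(A)
  stop(sprintf("'%s' must be an n x 2 coordinate matrix", name), call. = FALSE)
}

#' Directed Hausdorff distance
#'
#' \eqn{h(A, B) = \max_{a \in A} \min_{b \in B} \|a - b\|} with Euclidean
#' distance on pixel-center coordinates.  Not symmetric in general.
#'
#' @param A,B non-empty `n x 2` coordinate matrices (`row`, `col`).
#' @return distance in pixels.
#' @export
directed_hausdorff <- function(A, B) {
  A <- as_point_matrix(A, "A"); B <- as_point_matrix(B, "B")
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty", call. = FALSE)
  # chunk A so the cross-distance block stays small
  step <- max(1L, floor(2e6 / nrow(B)))
  worst <- 0
  for (s in seq(1, nrow(A), by = step)) {
    e <- min(nrow(A), s + step - 1)
    d2 <- outer(A[s:e, 1], B[, 1], "-")^2 + outer(A[s:e, 2], B[, 2], "-")^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}

#' Maximum (symmetric) Hausdorff distance
#'
#' \eqn{HD(A, B) = \max(h(A, B), h(B, A))}: the worst-case disagreement
#' between two point sets.  Symmetric, non-negative, zero iff the sets are
#' equal.
#'
#' @inheritParams directed_hausdorff
#' @return distance in pixels.
#' @export
max_hausdorff <- function(A, B) {
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Evaluate a segmentation against ground truth
#'
#' Dice is computed on the filled masks; the maximum Hausdorff distance on
#' the two boundary pixel sets ([mask_boundary()]), in pixel units on
#' pixel-center coordinates — the worst-case boundary error, which exposes
#' protrusions and recessions that Dice averages away.
#'
#' @param pred,truth logical matrices of identical dimensions; `truth`
#'   non-empty.
#' @param channel_label,phantom_id identifiers carried into the record.
#' @return one-row data frame with `phantom_id`, `channel`, `dice`,
#'   `max_hd`, `n_pred_pixels`, `n_truth_pixels`, `valid` (`FALSE` when the
#'   prediction is empty, in which case `dice = 0` and `max_hd = NA`).
#' @export
evaluate <- function(pred, truth, channel_label = "gray", phantom_id = NA_integer_) {
  if (!identical(dim(pred), dim(truth))) stop("mask dimensions differ", call. = FALSE)
  if (!any(truth)) stop("'truth' must be non-empty", call. = FALSE)
  if (!any(pred)) {
    return(data.frame(phantom_id = phantom_id, channel = channel_label,
                      dice = 0, max_hd = NA_real_,
                      n_pred_pixels = 0L, n_truth_pixels = sum(truth),
                      valid = FALSE, stringsAsFactors = FALSE))
  }
  d <- dice(pred, truth)
  hd <- max_hausdorff(mask_boundary(pred), mask_boundary(truth))
  data.frame(phantom_id = phantom_id, channel = channel_label,
             dice = d, max_hd = hd,
             n_pred_pixels = sum(pred), n_truth_pixels = sum(truth),
             valid = TRUE, stringsAsFactors = FALSE)
}
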