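#' Normalized mean square error between a reference and a test image
#'
#' `NMSE = sum(((I0 - mean(I0)) - (I - mean(I)))^2) / sum((I0 - mean(I0))^2)`.
#' Both images enter mean-removed, so a constant offset between them does not
#' register. Zero iff the mean-removed images are identical; lower is better.
#'
#' @param reference Clean image (numeric matrix).
#' @param test Processed image, same shape.
#' @return Non-negative scalar.
#' @export
nmse <- function(reference, test) {
  check_pair(reference, test)
  r <- reference - mean(reference)
  t_ <- test - mean(test)
  den <- sum(r^2)
  if (den == 0) abort("`reference` is constant; NMSE is undefined.")
  sum((r - t_)^2) / den
}

#' Noise-suppression measure (alpha)
#'
#' The mean-removed normalized cross-correlation between reference and test
#' intensities, i.e. the Pearson correlation of the pixel values. Lies in
#' `[-1, 1]`; equals 1 for any `test = a * reference + b` with `a > 0`.
#' Higher is better.
#'
#' @inheritParams nmse
#' @return Scalar in `[-1, 1]`.
#' @export
noise_suppression_alpha <- function(reference, test) {
  check_pair(reference, test)
  r <- reference - mean(reference)
  t_ <- test - mean(test)
  d1 <- sum(r^2); d2 <- sum(t_^2)
  if (d1 == 0) abort("`reference` is constant; alpha is undefined.")
  if (d2 == 0) abort("`test` is constant; alpha is undefined.")
  sum(r * t_) / sqrt(d1 * d2)
}

#' Edge-preservation measure (beta)
#'
#' Applies the 4-neighbour Laplacian to both images and returns the
#' mean-removed normalized cross-correlation of the two Laplacian fields,
#' evaluated on the interior pixels (where the full stencil exists). Lies in
#' `[-1, 1]`; 1 when the edge structure is perfectly preserved. Higher is
#' better.
#'
#' @inheritParams nmse
#' @return Scalar in `[-1, 1]`.
#' @export
edge_preservation_beta <- function(reference, test) {
  check_pair(reference, test)
  lr <- interior_laplacian(reference)
  lt <- interior_laplacian(test)
  r <- lr - mean(lr)
  t_ <- lt - mean(lt)
  d1 <- sum(r^2)
  if (d1 == 0) {
    abort("`reference` has an identically-zero Laplacian; beta is undefined.")
  }
  d2 <- sum(t_^2)
  if (d2 == 0) abort("`test` has an identically-zero Laplacian; beta is undefined.")
  sum(r * t_) / sqrt(d1 * d2)
}

# 4-neighbour Laplacian c = 4*I - (up + down + left + right) on the interior
# (rows 2..H-1, cols 2..W-1), where the full stencil is in bounds.
interior_laplacian <- function(img) {
  H <- nrow(img); W <- ncol(img)
  ctr <- img[2:(H - 1), 2:(W - 1)]
  4 * ctr -
    img[1:(H - 2), 2:(W - 1)] - img[3:H, 2:(W - 1)] -
    img[2:(H - 1), 1:(W - 2)] - img[2:(H - 1), 3:W]
}

check_pair <- function(reference, test) {
  check_image(reference, "reference")
  check_image(test, "test")
  if (!all(dim(reference) == dim(test))) {
    abort("`reference` and `test` must have identical dimensions.")
  }
  invisible(NULL)
}

#' Laplacian local contrast over a point set
#'
#' Mean absolute 4-neighbour Laplacian `|4 I(x,y) - sum of the 4 neighbours|`
#' over the supplied pixels. Low values over a homogeneous region indicate
#' good speckle suppression; high values over an edge set indicate good edge
#' preservation. The absolute value matters: raw Laplacians average toward
#' zero in homogeneous noise and would not discriminate.
#'
#' @param img Numeric matrix.
#' @param points Data frame with 1-based `row`, `col` columns; every point
#'   must have all four neighbours in bounds (no border pixels).
#' @return Non-negative scalar.
#' @export
laplacian_contrast <- function(img, points) {
  check_image(img)
  check_points(points)
  H <- nrow(img); W <- ncol(img)
  r <- points$row; c <- points$col
  bad <- which(r < 2 | r > H - 1 | c < 2 | c > W - 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "points without a full 4-neighbourhood (rows of `points`): %s",
      paste(bad, collapse = ", ")))
  }
  lap <- 4 * img[cbind(r, c)] -
    img[cbind(r - 1, c)] - img[cbind(r + 1, c)] -
    img[cbind(r, c - 1)] - img[cbind(r, c + 1)]
  mean(abs(lap))
}

#' Pratt's figure of merit for boundary accuracy
#'
#' `FOM = (1 / max(I_A, I_I)) * sum_i 1 / (1 + gamma * d(i)^2)`, where the
#' sum runs over the `I_I` reference-boundary pixels, `d(i)` is the Euclidean
#' distance from reference pixel `i` to the nearest of the `I_A`
#' automatically-extracted boundary pixels, and `gamma` scales the distance
#' penalty. Lies in `(0, 1]`; 1 iff the two pixel sets coincide. The
#' normalization by `max(I_A, I_I)` penalizes both under- and
#' over-segmentation.
#'
#' Note the asymmetry of the sum: distances are measured from reference
#' pixels to the automatic boundary, so swapping the arguments changes the
#' value (only the normalization is symmetric).
#'
#' @param auto Data frame of automatically-extracted boundary pixels
#'   (`row`, `col`).
#' @param reference Data frame of ground-truth boundary pixels (`row`, `col`).
#' @param gamma Positive scaling constant; 0.05 is the conventional choice.
#' @return Scalar in `(0, 1]`.
#' @examples
#' b <- tibble::tibble(row = c(1, 1, 2), col = c(1, 2, 2))
#' pratt_fom(b, b)  # 1
#' @export
pratt_fom <- function(auto, reference, gamma = 0.05) {
  check_points(auto, "auto")
  check_points(reference, "reference")
  if (gamma <= 0) abort("`gamma` must be positive.")
  d2 <- outer(reference$row, auto$row, `-`)^2 +
    outer(reference$col, auto$col, `-`)^2
  dmin2 <- apply(d2, 1, min)
  sum(1 / (1 + gamma * dmin2)) / max(nrow(auto), nrow(reference))
}

#' Despeckling quality report for one image pair
#'
#' Convenience wrapper computing [nmse()], [noise_suppression_alpha()] and
#' [edge_preservation_beta()] in one call.
#'
#' @inheritParams nmse
#' @return A one-row tibble with columns `nmse`, `alpha`, `beta`.
#' @export
metrics_report <- function(reference, test) {
  tibble::tibble(
    nmse = nmse(reference, test),
    alpha = noise_suppression_alpha(reference, test),
    beta = edge_preservation_beta(reference, test)
  )
}
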