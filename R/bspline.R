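#' B-spline blending function (Cox-de Boor recursion)
#'
#' Evaluates the order-`p` basis function `B_{i,p}(t)` over an arbitrary
#' non-decreasing knot sequence, with the usual 0/0 = 0 convention. Order 4
#' gives the cubic blending functions used by the snake contour.
#'
#' @param i Basis index, 0-based into `knots` (valid: `0 .. length(knots) - p - 1`).
#' @param p Order (degree + 1); `p = 1` is the piecewise-constant base case.
#' @param t Evaluation parameter; must lie within the knot range.
#' @param knots Non-decreasing numeric knot sequence `t_0 .. t_k`.
#' @return Non-negative scalar weight.
#' @export
bspline_basis <- function(i, p, t, knots) {
  if (is.unsorted(knots)) abort("`knots` must be non-decreasing.")
  if (t < knots[1] || t > knots[length(knots)]) {
    abort("`t` lies outside the knot range.")
  }
  if (i < 0 || i + p > length(knots) - 1) {
    abort("basis index `i` out of range for these knots.")
  }
  kn <- function(j) knots[j + 1]  # 0-based access
  rec <- function(i, p) {
    if (p == 1) {
      # half-open support, closed at the global right end
      return(as.numeric(t >= kn(i) &
                          (t < kn(i + 1) ||
                             (t == kn(i + 1) &&
                                kn(i + 1) == knots[length(knots)]))))
    }
    left <- 0
    if (kn(i + p - 1) > kn(i)) {
      left <- (t - kn(i)) / (kn(i + p - 1) - kn(i)) * rec(i, p - 1)
    }
    right <- 0
    if (kn(i + p) > kn(i + 1)) {
      right <- (kn(i + p) - t) / (kn(i + p) - kn(i + 1)) * rec(i + 1, p - 1)
    }
    left + right
  }
  rec(i, p)
}

#' Closed cubic B-spline contour
#'
#' A closed contour represented by `m >= 4` cyclic control points and a
#' uniform periodic knot spacing. The curve does not interpolate the control
#' points; its smoothness is what replaces explicit internal (tension /
#' rigidity) forces in the snake.
#'
#' @param control_points Numeric `m x 2` matrix of `(row, col)` subpixel
#'   coordinates.
#' @return An object of class `bspline_contour`.
#' @export
bspline_contour <- function(control_points) {
  control_points <- as.matrix(control_points)
  if (!is.numeric(control_points) || ncol(control_points) != 2 ||
      nrow(control_points) < 4) {
    abort("`control_points` must be a numeric m x 2 matrix with m >= 4.")
  }
  if (!all(is.finite(control_points))) {
    abort("`control_points` must be finite.")
  }
  m <- nrow(control_points)
  structure(list(control_points = control_points, order = 4L,
                 knots = seq(0, m + 4)),
            class = "bspline_contour")
}

#' Initialize a circular snake contour
#'
#' Places `n_ctrl` control points equally spaced on a circle. Because a
#' cubic B-spline lies inside the convex hull of its control polygon, the
#' sampled curve lies just inside the circle.
#'
#' @param center `(row, col)` circle centre in pixels.
#' @param radius Circle radius in pixels (> 2).
#' @param n_ctrl Number of control points; 48 is the packaged default.
#' @param image_dim Optional `(H, W)`; when given, the circle must lie fully
#'   inside the image.
#' @return A [bspline_contour()].
#' @export
init_circle <- function(center, radius, n_ctrl = 48L, image_dim = NULL) {
  if (radius <= 2) abort("`radius` must exceed 2 pixels.")
  if (n_ctrl < 4) abort("`n_ctrl` must be >= 4.")
  if (!is.null(image_dim)) {
    if (center[1] - radius < 1 || center[2] - radius < 1 ||
        center[1] + radius > image_dim[1] ||
        center[2] + radius > image_dim[2]) {
      abort("initialization circle extends outside the image.")
    }
  }
  theta <- 2 * pi * (seq_len(n_ctrl) - 1) / n_ctrl
  bspline_contour(cbind(center[1] + radius * sin(theta),
                        center[2] + radius * cos(theta)))
}

# Sampling matrix S (n x m): row j holds the four uniform periodic cubic
# basis weights of sample parameter t_j = (j-1) * m / n, cyclic in the
# control-point index. S %*% P gives the sampled curve.
contour_sampling_matrix <- function(m, n) {
  t_ <- (seq_len(n) - 1) * m / n
  seg <- floor(t_)              # segment 0 .. m-1
  u <- t_ - seg
  b <- cbind((1 - u)^3, 3 * u^3 - 6 * u^2 + 4,
             -3 * u^3 + 3 * u^2 + 3 * u + 1, u^3) / 6
  S <- matrix(0, n, m)
  for (k in 0:3) {
    idx <- ((seg + k - 1) %% m) + 1  # control P_{seg-1+k}, cyclic, 1-based
    S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] + b[, k + 1]
  }
  S
}

#' Sample a closed B-spline contour
#'
#' Evaluates the curve at `n` parameters evenly spaced over the closed
#' parameter range, one cubic segment per control point.
#'
#' @param contour A [bspline_contour()].
#' @param n Number of samples; at least the number of control points.
#' @return Tibble with subpixel `row`, `col` columns (a closed polyline; the
#'   first sample follows the last).
#' @export
sample_contour <- function(contour, n = 4L * nrow(contour$control_points)) {
  if (!inherits(contour, "bspline_contour")) {
    abort("`contour` must be a bspline_contour.")
  }
  m <- nrow(contour$control_points)
  if (n < m) abort("`n` must be at least the number of control points.")
  pts <- contour_sampling_matrix(m, n) %*% contour$control_points
  tibble::tibble(row = pts[, 1], col = pts[, 2])
}

#' Digital boundary of a closed contour
#'
#' Rasterizes the region enclosed by the curve (scanline fill of a dense
#' polygonal sampling) and returns its boundary pixels: region pixels with at
#' least one 4-neighbour outside the region. This convention is robust to
#' subpixel wobble of the curve, which naive rounding of curve samples is
#' not, and it is the same convention [boundary_pixels()] applies to a
#' ground-truth mask, so extracted and reference boundaries are directly
#' comparable with [pratt_fom()].
#'
#' @param contour A [bspline_contour()].
#' @param image_dim `(H, W)` of the pixel grid; defaults to the contour's
#'   bounding box.
#' @param n Polygon samples used for the fill.
#' @return Tibble of 1-based boundary pixels (`row`, `col`).
#' @export
rasterize_contour <- function(contour, image_dim = NULL,
                              n = 16L * nrow(contour$control_points)) {
  s <- sample_contour(contour, n)
  if (is.null(image_dim)) {
    image_dim <- c(ceiling(max(s$row)) + 1, ceiling(max(s$col)) + 1)
  }
  mask <- fill_polygon(s$row, s$col, image_dim[1], image_dim[2])
  boundary_pixels(mask)
}

#' Boundary pixels of a binary mask
#'
#' Pixels inside the mask with at least one 4-neighbour outside it (image
#' borders count as outside).
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Tibble of 1-based `row`, `col` boundary pixels.
#' @export
boundary_pixels <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_all <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  idx <- which(core & !nb_all, arr.ind = TRUE)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}
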