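#' Snake evolution parameters
#'
#' @param n_samples Curve samples per evolution step; forces are read at
#'   these points and projected back onto the control points.
#' @param step_size Force-to-displacement gain (pixels per unit force).
#' @param max_iters Iteration cap.
#' @param tol Convergence threshold: stop when the largest control-point
#'   displacement in a step falls below `tol` pixels (must be < 1).
#' @param gvf_k Edge-gating parameter passed to [compute_gvf()]; the default
#'   0.05 is the customary choice for edge maps normalized to `[0, 1]` and
#'   keeps the field pinned to genuine (including speckle-induced) edges.
#' @param gvf_iters Diffusion iterations passed to [compute_gvf()].
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(n_samples = 192L, step_size = 2, max_iters = 500L,
                         tol = 0.02, gvf_k = 0.05, gvf_iters = 80L) {
  if (n_samples < 4) abort("`n_samples` must be >= 4.")
  if (step_size <= 0) abort("`step_size` must be positive.")
  if (max_iters < 1) abort("`max_iters` must be >= 1.")
  if (tol <= 0 || tol >= 1) abort("`tol` must lie in (0, 1) pixels.")
  if (gvf_k <= 0) abort("`gvf_k` must be positive.")
  if (gvf_iters < 1) abort("`gvf_iters` must be >= 1.")
  structure(list(n_samples = as.integer(n_samples), step_size = step_size,
                 max_iters = as.integer(max_iters), tol = tol,
                 gvf_k = gvf_k, gvf_iters = as.integer(gvf_iters)),
            class = "snake_params")
}

#' Evolve a B-spline snake in a GVF force field
#'
#' Iteratively: sample the closed contour at `n_samples` points, read the
#' `(u, v)` external force at each sample by bilinear interpolation (border
#' clamped), project the sampled forces back onto the control points through
#' the least-squares (pseudo-inverse) fit of the B-spline sampling matrix,
#' and move the control points by `step_size` times the projected force.
#' Stops when the largest control-point displacement drops below `tol`
#' pixels or `max_iters` is reached. Smoothness comes from the B-spline
#' representation itself; no explicit internal forces are used.
#'
#' @param contour Initial [bspline_contour()] (e.g. from [init_circle()]).
#' @param field A [compute_gvf()] field sharing the image frame.
#' @param params A [snake_params()].
#' @return An object of class `bspline_snake`: list with the final
#'   `contour`, `iterations` run, and `converged` flag.
#' @examples
#' img <- matrix(0.1, 96, 96); img[outer((1:96 - 48)^2, (1:96 - 48)^2, "+")
#'   <= 20^2] <- 0.9
#' fld <- compute_gvf(edge_map(img), k = 0.5, iters = 80)
#' fit <- evolve_snake(init_circle(c(48, 48), 10), fld, snake_params())
#' glance(fit)
#' @export
evolve_snake <- function(contour, field, params = snake_params()) {
  if (!inherits(contour, "bspline_contour")) {
    abort("`contour` must be a bspline_contour.")
  }
  if (!inherits(field, "gvf_field")) {
    abort("`field` must be a gvf_field from compute_gvf().")
  }
  if (!inherits(params, "snake_params")) {
    abort("`params` must be created with snake_params().")
  }
  H <- nrow(field$u); W <- ncol(field$u)
  m <- nrow(contour$control_points)
  n <- max(params$n_samples, m)
  S <- contour_sampling_matrix(m, n)
  proj <- solve(crossprod(S), t(S))  # least-squares back-projection
  P <- contour$control_points
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iters)) {
    iters <- it
    pts <- S %*% P
    if (any(pts[, 1] < 0.5 | pts[, 1] > H + 0.5 |
            pts[, 2] < 0.5 | pts[, 2] > W + 0.5)) {
      cnd <- rlang::error_cnd(
        "follikel_snake_escape",
        message = sprintf("contour escaped the image frame at iteration %d", it),
        last_contour = bspline_contour(P))
      rlang::cnd_signal(cnd)
    }
    force <- cbind(interp_bilinear(field$v, pts[, 1], pts[, 2]),
                   interp_bilinear(field$u, pts[, 1], pts[, 2]))
    dP <- params$step_size * (proj %*% force)
    P <- P + dP
    if (max(abs(dP)) < params$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(contour = bspline_contour(P), iterations = iters,
                 converged = converged, params = params),
            class = "bspline_snake")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted snake: its control points
#'
#' @param x A `bspline_snake`.
#' @param ... Unused.
#' @return Tibble with `point` index and subpixel `row`, `col` of each
#'   control point of the final contour.
#' @export
tidy.bspline_snake <- function(x, ...) {
  cp <- x$contour$control_points
  tibble::tibble(point = seq_len(nrow(cp)), row = cp[, 1], col = cp[, 2])
}

#' One-row summary of a snake fit
#'
#' @param x A `bspline_snake`.
#' @param ... Unused.
#' @return Tibble with `n_control`, `iterations`, `converged`.
#' @export
glance.bspline_snake <- function(x, ...) {
  tibble::tibble(n_control = nrow(x$contour$control_points),
                 iterations = x$iterations, converged = x$converged)
}

#' Plot a fitted snake contour
#'
#' @param object A `bspline_snake`.
#' @param ... Unused.
#' @return A ggplot of the sampled closed curve and its control points.
#' @export
autoplot.bspline_snake <- function(object, ...) {
  s <- sample_contour(object$contour)
  s <- rbind(s, s[1, ])
  cp <- tidy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = cp, shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
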