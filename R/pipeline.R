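#' Segment one follicle with the B-spline GVF snake
#'
#' Composes the segmentation stages: edge map of the (already despeckled)
#' image, GVF diffusion, circular initialization inside the follicle, and
#' snake evolution. Initialization is user-supplied — a circle centred
#' inside the target follicle — as automatic detection is out of scope.
#'
#' @param img Numeric matrix (ideally despeckled first).
#' @param center `(row, col)` of the initialization circle.
#' @param radius Initialization radius in pixels (inside the follicle).
#' @param params A [snake_params()].
#' @param n_ctrl Control points on the contour; default 48.
#' @param edge_sigma Pre-smoothing width for [edge_map()].
#' @return A `bspline_snake` (see [evolve_snake()]).
#' @export
segment_follicle <- function(img, center, radius, params = snake_params(),
                             n_ctrl = 48L, edge_sigma = 1) {
  check_image(img)
  f <- edge_map(img, sigma = edge_sigma)
  field <- compute_gvf(f, k = params$gvf_k, iters = params$gvf_iters)
  c0 <- init_circle(center, radius, n_ctrl = n_ctrl, image_dim = dim(img))
  evolve_snake(c0, field, params)
}

# Scanline fill of a closed polygon (subpixel vertices, 1-based pixel grid).
fill_polygon <- function(poly_row, poly_col, H, W) {
  mask <- matrix(FALSE, H, W)
  n <- length(poly_row)
  nxt <- c(2:n, 1)
  for (r in seq_len(H)) {
    y1 <- poly_row; y2 <- poly_row[nxt]
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crosses)) next
    tt <- (r - y1[crosses]) / (y2[crosses] - y1[crosses])
    xs <- sort(poly_col[crosses] + tt * (poly_col[nxt][crosses] - poly_col[crosses]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[i])); c1 <- min(W, floor(xs[i + 1]))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

#' Run the despeckle-and-segment pipeline on one image
#'
#' Filters the input (normalized or conventional bilateral, Gaussian
#' baseline, or no filtering), segments one follicle with the B-spline GVF
#' snake, and — when a reference boundary is supplied — scores the extracted
#' boundary with Pratt's figure of merit. Optionally writes the filtered
#' image, the boundary CSV, a binary mask PNG, and a JSON sidecar recording
#' every parameter.
#'
#' @param input Image path (see [read_image()]) or numeric matrix.
#' @param init_center,init_radius Snake initialization circle.
#' @param mode One of `"normalized"`, `"conventional"`, `"gaussian"`,
#'   `"none"`.
#' @param sigma_d,sigma_r,iterations Bilateral parameters (bilateral modes).
#' @param gaussian_sigma,gaussian_window Gaussian-baseline parameters.
#' @param snake A [snake_params()].
#' @param n_ctrl Contour control points.
#' @param reference Optional reference boundary (data frame `row`, `col`,
#'   1-based, or a CSV path) for FOM scoring.
#' @param gamma FOM scaling constant.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Seed recorded in the sidecar (the pipeline itself is
#'   deterministic; the seed documents the provenance of `input`).
#' @return One-row tibble: parameters, snake diagnostics, `fom` (NA without
#'   a reference) and artifact paths (NA when `out_dir` is NULL).
#' @export
run_pipeline <- function(input, init_center, init_radius,
                         mode = c("normalized", "conventional",
                                  "gaussian", "none"),
                         sigma_d = 3, sigma_r = 0.7, iterations = 5L,
                         gaussian_sigma = 3, gaussian_window = 9L,
                         snake = snake_params(), n_ctrl = 48L,
                         reference = NULL, gamma = 0.05,
                         out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  img <- if (is.character(input)) read_image(input) else input
  check_image(img)
  filtered <- switch(mode,
    normalized = ,
    conventional = bilateral_filter(img, bilateral_params(
      sigma_d = sigma_d, sigma_r = sigma_r, mode = mode,
      iterations = iterations)),
    gaussian = gaussian_filter(img, gaussian_sigma, gaussian_window),
    none = img
  )
  fit <- segment_follicle(filtered, init_center, init_radius,
                          params = snake, n_ctrl = n_ctrl)
  boundary <- rasterize_contour(fit$contour, dim(img))
  fom <- NA_real_
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_boundary(reference)
    fom <- pratt_fom(boundary, reference, gamma = gamma)
  }
  paths <- c(filtered = NA_character_, boundary = NA_character_,
             mask = NA_character_, sidecar = NA_character_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths["filtered"] <- file.path(out_dir, "filtered.tif")
    write_image(filtered, paths[["filtered"]])
    paths["boundary"] <- file.path(out_dir, "boundary.csv")
    write_boundary(boundary, paths[["boundary"]])
    s <- sample_contour(fit$contour, 16L * n_ctrl)
    mask <- fill_polygon(s$row, s$col, nrow(img), ncol(img))
    paths["mask"] <- file.path(out_dir, "mask.png")
    write_image(mask * 1, paths[["mask"]])
    paths["sidecar"] <- file.path(out_dir, "pipeline.json")
    jsonlite::write_json(list(
      mode = mode, sigma_d = sigma_d, sigma_r = sigma_r,
      iterations = iterations, gaussian_sigma = gaussian_sigma,
      gaussian_window = gaussian_window, init_center = init_center,
      init_radius = init_radius, n_ctrl = n_ctrl, gamma = gamma,
      seed = seed, snake = unclass(snake),
      snake_iterations = fit$iterations, converged = fit$converged,
      fom = fom), paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  }
  tibble::tibble(mode = mode, sigma_d = sigma_d, sigma_r = sigma_r,
                 iterations = as.integer(iterations),
                 snake_iterations = fit$iterations,
                 converged = fit$converged, fom = fom,
                 n_boundary = nrow(boundary),
                 filtered_path = paths[["filtered"]],
                 boundary_path = paths[["boundary"]],
                 mask_path = paths[["mask"]],
                 sidecar_path = paths[["sidecar"]])
}
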