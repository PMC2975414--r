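#' Describe a circle for a phantom specification
#'
#' @param center Numeric length-2, `(row, col)` centre in pixels (1-based).
#' @param radius Circle radius in pixels.
#' @param level Intensity level in `[0, 1]`.
#' @return A shape description list used by [phantom_spec()].
#' @export
shape_circle <- function(center, radius, level) {
  list(kind = "circle", center = as.numeric(center),
       radius = as.numeric(radius), level = as.numeric(level))
}

#' Describe an axis-aligned rectangle for a phantom specification
#'
#' Extents are half-open: the rectangle covers rows
#' `corner[1] .. corner[1] + size[1] - 1` and likewise for columns.
#'
#' @param corner Numeric length-2, `(row, col)` of the top-left pixel (1-based).
#' @param size Numeric length-2, `(height, width)` in pixels.
#' @param level Intensity level in `[0, 1]`.
#' @return A shape description list used by [phantom_spec()].
#' @export
shape_rectangle <- function(corner, size, level) {
  list(kind = "rectangle", corner = as.numeric(corner),
       size = as.numeric(size), level = as.numeric(level))
}

#' Specify a piecewise-constant phantom image
#'
#' A phantom is a constant background with circles and rectangles painted on
#' top, in list order. Rasterization is deterministic: a pixel belongs to a
#' circle iff its centre lies within the radius; rectangle extents are
#' half-open.
#'
#' @param canvas Integer length-2, `(height, width)` in pixels.
#' @param background Background intensity in `[0, 1]`.
#' @param shapes List of shapes from [shape_circle()] / [shape_rectangle()].
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [default_phantom_spec()]
#' @export
phantom_spec <- function(canvas = c(256L, 256L), background = 0.15,
                         shapes = list()) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2 || any(canvas < 3)) {
    abort("`canvas` must be two integers, each >= 3.")
  }
  if (background < 0 || background > 1) {
    abort("`background` must lie in [0, 1].")
  }
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    if (s$level < 0 || s$level > 1) {
      abort(sprintf("shape %d: intensity level must lie in [0, 1].", i))
    }
    if (s$kind == "circle") {
      if (s$radius <= 0) abort(sprintf("shape %d: radius must be positive.", i))
      lo <- s$center - s$radius; hi <- s$center + s$radius
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > canvas[1] || hi[2] > canvas[2]) {
        abort(sprintf("shape %d (circle) extends outside the canvas.", i))
      }
    } else if (s$kind == "rectangle") {
      if (any(s$size < 1)) abort(sprintf("shape %d: size must be >= 1.", i))
      hi <- s$corner + s$size - 1
      if (s$corner[1] < 1 || s$corner[2] < 1 ||
          hi[1] > canvas[1] || hi[2] > canvas[2]) {
        abort(sprintf("shape %d (rectangle) extends outside the canvas.", i))
      }
    } else {
      abort(sprintf("shape %d: unknown kind '%s'.", i, s$kind))
    }
  }
  structure(list(canvas = canvas, background = background, shapes = shapes),
            class = "phantom_spec")
}

#' The packaged default phantom
#'
#' A 256x256 test pattern of circles (radii 6, 12, 24) and squares (sides 5,
#' 15, 31) at two foreground intensities (0.5 and 0.9) on a darker background
#' (0.15), so that both high-intensity and low-intensity regions of several
#' object sizes are present. It is the standard input for the speckle
#' filtering experiments shipped with the package.
#'
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function() {
  phantom_spec(
    canvas = c(256L, 256L), background = 0.15,
    shapes = list(
      shape_circle(center = c(61, 61), radius = 24, level = 0.9),
      shape_circle(center = c(61, 151), radius = 12, level = 0.5),
      shape_circle(center = c(61, 211), radius = 6, level = 0.9),
      shape_rectangle(corner = c(151, 41), size = c(31, 31), level = 0.5),
      shape_rectangle(corner = c(161, 131), size = c(15, 15), level = 0.9),
      shape_rectangle(corner = c(166, 201), size = c(5, 5), level = 0.5)
    )
  )
}

#' Rasterize a phantom specification into an image
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix with intensities in `[0, 1]`.
#' @examples
#' img <- generate_phantom(default_phantom_spec())
#' sort(unique(as.vector(img)))
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    abort("`spec` must be created with phantom_spec().")
  }
  H <- spec$canvas[1]; W <- spec$canvas[2]
  img <- matrix(spec$background, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (s in spec$shapes) {
    if (s$kind == "circle") {
      inside <- (rows - s$center[1])^2 + (cols - s$center[2])^2 <= s$radius^2
      img[inside] <- s$level
    } else {
      r <- s$corner[1]:(s$corner[1] + s$size[1] - 1)
      c <- s$corner[2]:(s$corner[2] + s$size[2] - 1)
      img[r, c] <- s$level
    }
  }
  img
}

#' A two-follicle segmentation phantom
#'
#' Emulates the segmentation use case: two hypoechoic (dark) follicles in
#' brighter tissue, with a narrow 3-pixel tissue bridge between them so that
#' aggressive blurring merges their boundaries. The main follicle is the
#' radius-20 disk centred at `(64, 56)`; its true boundary is obtained with
#' `boundary_pixels(...)` on the corresponding disk mask.
#'
#' @return A `phantom_spec` (128x128, tissue 0.5, follicle level 0.12).
#' @export
follicle_phantom_spec <- function() {
  phantom_spec(
    canvas = c(128L, 128L), background = 0.5,
    shapes = list(
      shape_circle(center = c(64, 56), radius = 20, level = 0.12),
      shape_circle(center = c(64, 91), radius = 12, level = 0.12)
    )
  )
}

#' Parameters of the multiplicative speckle model
#'
#' Observed intensity is modelled as `J = I * (1 + eta)` with `eta` i.i.d.,
#' zero-mean by default. Under this model noise amplitude scales with signal
#' intensity, so speckle appears much stronger in bright regions than in dark
#' ones.
#'
#' @param mean Mean of the perturbation `eta` (dimensionless).
#' @param variance Variance of `eta`; the experiments in this package default
#'   to 0.075.
#' @param distribution `"uniform"` (eta ~ U(-a, a), a = sqrt(3*variance),
#'   matching the common `imnoise`-style speckle generator) or `"gaussian"`.
#' @return An object of class `speckle_params`.
#' @export
speckle_params <- function(mean = 0, variance = 0.075,
                           distribution = c("uniform", "gaussian")) {
  distribution <- match.arg(distribution)
  if (variance < 0) abort("`variance` must be non-negative.")
  if (distribution == "uniform" && variance > 1 / 3) {
    abort("uniform perturbations require `variance` <= 1/3.")
  }
  structure(list(mean = mean, variance = variance,
                 distribution = distribution),
            class = "speckle_params")
}

#' Corrupt an image with multiplicative speckle
#'
#' Applies `J(X) = I(X) * (1 + eta(X))` pixelwise with `eta` drawn i.i.d.
#' from the configured distribution, then (by default) clips to `[0, 1]`.
#' A zero pixel stays exactly zero: multiplicative noise vanishes on zero
#' signal.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param params A [speckle_params()].
#' @param seed Optional integer; when given, output is reproducible and the
#'   caller's RNG stream is left untouched.
#' @param clip Clip the result to `[0, 1]`? Set `FALSE` when measuring the
#'   noise moments, to avoid censoring bias at the range limits.
#' @return Numeric matrix, same shape as `img`.
#' @examples
#' clean <- generate_phantom(default_phantom_spec())
#' noisy <- apply_speckle(clean, speckle_params(variance = 0.075), seed = 1)
#' @export
apply_speckle <- function(img, params = speckle_params(), seed = NULL,
                          clip = TRUE) {
  check_image(img)
  if (!inherits(params, "speckle_params")) {
    abort("`params` must be created with speckle_params().")
  }
  n <- length(img)
  eta <- with_seed(seed, {
    if (params$distribution == "uniform") {
      a <- sqrt(3 * params$variance)
      params$mean + runif(n, -a, a)
    } else {
      rnorm(n, params$mean, sqrt(params$variance))
    }
  })
  out <- img * (1 + matrix(eta, nrow(img), ncol(img)))
  if (clip) out <- clamp01(out)
  out
}
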