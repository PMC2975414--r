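#' Bilateral filter parameters
#'
#' The bilateral filter replaces each pixel by a weighted mean of its
#' neighbourhood, with weights that fall off with both spatial distance
#' (Gaussian of width `sigma_d`) and intensity difference (Gaussian of width
#' `sigma_r`). Two range distances are supported:
#'
#' * `mode = "conventional"`: `D = |J(Y) - J(X)|`, the classic
#'   Tomasi-Manduchi filter, appropriate for additive noise.
#' * `mode = "normalized"`: `D = |J(Y) - J(X)| / max(|J(X)|, epsilon)`, the
#'   speckle-reducing variant. Under a multiplicative noise model the
#'   intensity difference inside a homogeneous region is proportional to the
#'   region's brightness; dividing by the centre-pixel intensity makes the
#'   range kernel see only the relative (noise-driven) fluctuation, so one
#'   `sigma_r` smooths bright and dark regions equally.
#'
#' @param sigma_d Spatial fall-off in pixels (> 0).
#' @param sigma_r Range fall-off; intensity units in conventional mode,
#'   relative-intensity units in normalized mode (> 0, `Inf` allowed).
#' @param half_width Neighbourhood radius in pixels; the window is
#'   `(2*half_width+1)^2`. Defaults to the 3-sigma truncation
#'   `ceiling(3 * sigma_d)`.
#' @param mode `"normalized"` or `"conventional"`.
#' @param iterations Number of filtering passes (>= 1); each pass feeds on
#'   the previous output with unchanged parameters.
#' @param epsilon Floor for the normalizing denominator (guards zero pixels);
#'   default 1/255.
#' @return An object of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_d = 3, sigma_r = 0.7,
                             half_width = ceiling(3 * sigma_d),
                             mode = c("normalized", "conventional"),
                             iterations = 1L, epsilon = 1 / 255) {
  mode <- match.arg(mode)
  if (sigma_d <= 0) abort("`sigma_d` must be positive.")
  if (sigma_r <= 0) abort("`sigma_r` must be positive.")
  if (half_width < 1) abort("`half_width` must be >= 1.")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r,
                 half_width = as.integer(half_width), mode = mode,
                 iterations = as.integer(iterations), epsilon = epsilon),
            class = "bilateral_params")
}

#' Bilateral weights for a single window
#'
#' Diagnostic helper exposing the weight patch the filter uses at one pixel:
#' `w(Y) = exp(-||X-Y||^2 / (2 sigma_d^2)) * exp(-D^2 / (2 sigma_r^2))` with
#' the mode-dependent range distance `D` (see [bilateral_params()]).
#'
#' @param window Square numeric matrix of odd side `2*half_width + 1`.
#' @param params A [bilateral_params()]; `params$half_width` must match the
#'   window.
#' @param center_value The intensity the window is centred on; must equal the
#'   window's central element (contract check).
#' @return Matrix of unnormalized weights, same shape as `window`. The sum of
#'   the patch is the normalizing constant `C`.
#' @export
bilateral_weights <- function(window, params,
                              center_value = window[params$half_width + 1,
                                                    params$half_width + 1]) {
  h <- params$half_width
  if (!is.matrix(window) || nrow(window) != 2 * h + 1 ||
      ncol(window) != 2 * h + 1) {
    abort("`window` must be a square matrix of side 2*half_width + 1.")
  }
  centre <- window[h + 1, h + 1]
  if (!isTRUE(all.equal(center_value, centre))) {
    abort("`center_value` does not equal the window's central pixel.")
  }
  d2 <- outer((-h:h)^2, (-h:h)^2, `+`)
  spatial <- exp(-d2 / (2 * params$sigma_d^2))
  D <- abs(window - centre)
  if (params$mode == "normalized") {
    D <- D / max(abs(centre), params$epsilon)
  }
  spatial * exp(-D^2 / (2 * params$sigma_r^2))
}

#' Filter an image with the (iterative) bilateral filter
#'
#' Applies `params$iterations` passes of the selected bilateral filter, each
#' pass consuming the previous pass's output with unchanged parameters.
#' Boundaries are handled by symmetric reflection. Every pass is a convex
#' combination of input intensities, so the output stays within the input's
#' `[min, max]`.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param params A [bilateral_params()].
#' @param keep_intermediate Logical; when `TRUE` the per-iteration images are
#'   attached as the `"snapshots"` attribute (a list) for diagnostics.
#' @return Filtered numeric matrix, same shape as `img`.
#' @examples
#' noisy <- apply_speckle(generate_phantom(default_phantom_spec()), seed = 1)
#' smooth <- bilateral_filter(noisy,
#'   bilateral_params(sigma_d = 3, sigma_r = 0.7, iterations = 5))
#' @export
bilateral_filter <- function(img, params = bilateral_params(),
                             keep_intermediate = FALSE) {
  check_image(img)
  if (!inherits(params, "bilateral_params")) {
    abort("`params` must be created with bilateral_params().")
  }
  if (params$half_width >= min(dim(img))) {
    abort("`half_width` must be smaller than the image's smallest dimension.")
  }
  out <- img
  snaps <- if (keep_intermediate) vector("list", params$iterations)
  for (it in seq_len(params$iterations)) {
    out <- bilateral_pass_cpp(out, params$sigma_d, params$sigma_r,
                              params$half_width,
                              params$mode == "normalized", params$epsilon)
    if (keep_intermediate) snaps[[it]] <- out
  }
  if (keep_intermediate) attr(out, "snapshots") <- snaps
  out
}

#' Gaussian smoothing baseline
#'
#' Plain separable Gaussian convolution with a truncated, renormalized
#' kernel and symmetric-reflection boundaries. Included as the trivial
#' reference filter against which the bilateral variants are compared; it is
#' also, by construction, the `sigma_r -> Inf` limit of the conventional
#' bilateral filter with the same window.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation of the Gaussian kernel in pixels.
#' @param window Full window size (odd); default 9.
#' @return Smoothed numeric matrix.
#' @export
gaussian_filter <- function(img, sigma = 3, window = 9) {
  check_image(img)
  if (sigma <= 0) abort("`sigma` must be positive.")
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) abort("`window` must be odd and >= 1.")
  h <- (window - 1L) %/% 2L
  if (h >= min(dim(img))) abort("`window` too large for this image.")
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) {
    idx <- c(h:1, seq_len(n), n:(n - h + 1))
    if (h == 0) idx <- seq_len(n)
    idx
  }
  conv_cols <- function(m) {
    # convolve each column with k, symmetric padding
    padded <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(2 * h + 1)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}
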