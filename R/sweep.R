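#' Specify a range-parameter sweep experiment
#'
#' Describes the standard experiment: corrupt a phantom with multiplicative
#' speckle, filter it with each mode at every `sigma_r`, and score the
#' result against the clean phantom with NMSE / alpha / beta. `sigma_d` stays
#' fixed while `sigma_r` is swept.
#'
#' @param sigma_r_values Ordered vector of range fall-off values.
#' @param sigma_d Fixed spatial fall-off (pixels).
#' @param iterations Filtering passes per run.
#' @param modes Subset of `c("conventional", "normalized")`.
#' @param seeds Integer vector; one noise realization per seed.
#' @param phantom A [phantom_spec()].
#' @param noise A [speckle_params()].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(sigma_r_values = seq(0.1, 1.0, by = 0.1),
                       sigma_d = 3, iterations = 5L,
                       modes = c("conventional", "normalized"),
                       seeds = 1:5,
                       phantom = default_phantom_spec(),
                       noise = speckle_params()) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (length(sigma_r_values) == 0 || any(sigma_r_values <= 0)) {
    abort("`sigma_r_values` must be a non-empty vector of positive values.")
  }
  if (sigma_d <= 0) abort("`sigma_d` must be positive.")
  if (length(seeds) == 0) abort("`seeds` must be non-empty.")
  structure(list(sigma_r_values = sigma_r_values, sigma_d = sigma_d,
                 iterations = as.integer(iterations), modes = modes,
                 seeds = as.integer(seeds), phantom = phantom, noise = noise),
            class = "sweep_spec")
}

#' Run a sigma_r sweep
#'
#' For every `(mode, sigma_r, seed)` triple: generate the phantom, corrupt
#' it (seeded), filter, and compute the quality metrics against the clean
#' phantom. A failing run is recorded with `NA` metrics and its error
#' message; the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param .progress Print one line per completed (mode, sigma_r) pair?
#' @return A tibble of class `follikel_sweep` with one row per triple:
#'   `mode`, `sigma_r`, `seed`, `nmse`, `alpha`, `beta`, `elapsed` (seconds),
#'   `error` (NA on success).
#' @seealso [sweep_optima()], [autoplot.follikel_sweep()]
#' @export
run_sweep <- function(spec, .progress = FALSE) {
  if (!inherits(spec, "sweep_spec")) {
    abort("`spec` must be created with sweep_spec().")
  }
  clean <- generate_phantom(spec$phantom)
  grid <- tidyr::expand_grid(seed = spec$seeds, mode = spec$modes,
                             sigma_r = spec$sigma_r_values)
  noisy_cache <- lapply(stats::setNames(spec$seeds, spec$seeds), function(s) {
    apply_speckle(clean, spec$noise, seed = s)
  })
  res <- purrr::pmap(grid, function(seed, mode, sigma_r) {
    noisy <- noisy_cache[[as.character(seed)]]
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      filt <- bilateral_filter(noisy, bilateral_params(
        sigma_d = spec$sigma_d, sigma_r = sigma_r, mode = mode,
        iterations = spec$iterations))
      cbind(metrics_report(clean, filt),
            tibble::tibble(error = NA_character_))
    }, error = function(e) {
      tibble::tibble(nmse = NA_real_, alpha = NA_real_, beta = NA_real_,
                     error = conditionMessage(e))
    })
    rec$elapsed <- proc.time()[["elapsed"]] - t0
    if (isTRUE(.progress)) {
      message(sprintf("sweep: mode=%s sigma_r=%.2f seed=%d (%.1fs)",
                      mode, sigma_r, seed, rec$elapsed))
    }
    rec
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out <- out[, c("mode", "sigma_r", "seed", "nmse", "alpha", "beta",
                 "elapsed", "error")]
  class(out) <- c("follikel_sweep", class(out))
  attr(out, "spec") <- spec
  out
}

#' Per-mode optimal operating point of a sweep
#'
#' The optimal point is the `sigma_r` maximizing the edge-preservation
#' measure beta (seed-averaged).
#'
#' @param sweep A [run_sweep()] result.
#' @return Tibble with one row per mode: `mode`, `sigma_r_opt`, and the
#'   seed-mean `nmse`, `alpha`, `beta` at the optimum.
#' @export
sweep_optima <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$mode, .data$sigma_r) |>
    dplyr::summarise(nmse = mean(.data$nmse), alpha = mean(.data$alpha),
                     beta = mean(.data$beta), .groups = "drop_last") |>
    dplyr::slice_max(.data$beta, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(sigma_r_opt = "sigma_r")
}

#' Plot sweep curves
#'
#' Seed-averaged NMSE, alpha and beta against `sigma_r`, one panel per
#' metric, coloured by filter mode.
#'
#' @param object A `follikel_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.follikel_sweep <- function(object, ...) {
  long <- object |>
    dplyr::group_by(.data$mode, .data$sigma_r) |>
    dplyr::summarise(nmse = mean(.data$nmse), alpha = mean(.data$alpha),
                     beta = mean(.data$beta), .groups = "drop") |>
    tidyr::pivot_longer(c("nmse", "alpha", "beta"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sigma_r, y = .data$value,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(sigma[r]), y = NULL, colour = "filter")
}
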