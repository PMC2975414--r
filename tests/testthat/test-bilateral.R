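test_that("weight patches follow the two range-distance definitions", {
  p_conv <- bilateral_params(sigma_d = 1, sigma_r = 0.3, half_width = 1,
                             mode = "conventional")
  p_norm <- bilateral_params(sigma_d = 1, sigma_r = 0.3, half_width = 1,
                             mode = "normalized")
  # constant patch: range factor 1 everywhere, weights = spatial Gaussian
  const <- matrix(0.4, 3, 3)
  spatial <- exp(-outer((-1:1)^2, (-1:1)^2, `+`) / 2)
  expect_equal(bilateral_weights(const, p_conv), spatial, tolerance = 1e-12)
  expect_equal(bilateral_weights(const, p_norm), spatial, tolerance = 1e-12)
  # one neighbour differing by 0.1 from a 0.5 centre (scalar oracle)
  patch <- matrix(0.5, 3, 3); patch[2, 3] <- 0.6
  w_conv <- bilateral_weights(patch, p_conv)
  expect_equal(w_conv[2, 3], exp(-1 / 2) * exp(-0.1^2 / (2 * 0.3^2)),
               tolerance = 1e-12)
  w_norm <- bilateral_weights(patch, p_norm)
  expect_equal(w_norm[2, 3], exp(-1 / 2) * exp(-(0.1 / 0.5)^2 / (2 * 0.3^2)),
               tolerance = 1e-12)
  # the normalized range factor is strictly smaller here (centre < 1)
  expect_lt(w_norm[2, 3], w_conv[2, 3])
  # central weight is the patch maximum and the patch sums to C > 0
  expect_equal(which.max(w_conv), 5L)
  expect_gt(sum(w_conv), 0)
  # centre-value contract
  expect_error(bilateral_weights(patch, p_conv, center_value = 0.9),
               "central pixel")
})

test_that("both filters match the exhaustive brute-force oracle", {
  for (seed in c(1, 2)) {
    img <- random_image(12, 16, seed)
    for (mode in c("conventional", "normalized")) {
      p <- bilateral_params(sigma_d = 1.5, sigma_r = 0.25, half_width = 3,
                            mode = mode)
      got <- bilateral_filter(img, p)
      want <- bf_bilateral(img, 1.5, 0.25, 3, mode == "normalized")
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("constant images are exact fixed points of both filters", {
  img <- matrix(0.37, 10, 10)
  for (mode in c("conventional", "normalized")) {
    out <- bilateral_filter(img, bilateral_params(
      sigma_d = 2, sigma_r = 0.4, half_width = 3, mode = mode,
      iterations = 3))
    expect_equal(out, img, tolerance = 1e-14)
  }
})

test_that("sigma_r -> Inf degenerates to plain Gaussian smoothing", {
  img <- random_image(20, 24, 9)
  p <- bilateral_params(sigma_d = 3, sigma_r = Inf, half_width = 4,
                        mode = "conventional")
  expect_equal(bilateral_filter(img, p), gaussian_filter(img, 3, 9),
               tolerance = 1e-6)
})

test_that("sigma_r -> 0+ approaches the identity", {
  # quantized intensities: pixel differences are 0 or >= 1/9, both of which
  # leave the centre pixel untouched as the range kernel collapses
  img <- round(9 * random_image(10, 10, 21)) / 9
  p <- bilateral_params(sigma_d = 2, sigma_r = 1e-3, half_width = 2,
                        mode = "conventional")
  expect_lt(max(abs(bilateral_filter(img, p) - img)), 1e-8)
})

test_that("output is a convex combination: min-max bounds hold every pass", {
  for (seed in 3:5) {
    img <- random_image(16, 16, seed)
    for (mode in c("conventional", "normalized")) {
      out <- bilateral_filter(img, bilateral_params(
        sigma_d = 2, sigma_r = 0.5, half_width = 3, mode = mode,
        iterations = 3))
      expect_gte(min(out), min(img))
      expect_lte(max(out), max(img))
    }
  }
})

test_that("filtering commutes with transposition and flips", {
  img <- random_image(14, 18, 8)
  p <- bilateral_params(sigma_d = 2, sigma_r = 0.3, half_width = 3)
  out <- bilateral_filter(img, p)
  expect_equal(bilateral_filter(t(img), p), t(out), tolerance = 1e-13)
  flip <- img[nrow(img):1, ]
  expect_equal(bilateral_filter(flip, p), out[nrow(out):1, ],
               tolerance = 1e-13)
})

test_that("the normalized range kernel is scale invariant, the conventional is not", {
  img <- 0.2 + 0.8 * random_image(12, 12, 13)  # bounded away from zero
  s <- 0.5
  p_norm <- bilateral_params(sigma_d = 2, sigma_r = 0.4, half_width = 3,
                             mode = "normalized", epsilon = 1e-12)
  expect_equal(bilateral_filter(s * img, p_norm),
               s * bilateral_filter(img, p_norm), tolerance = 1e-12)
  p_conv <- bilateral_params(sigma_d = 2, sigma_r = 0.4, half_width = 3,
                             mode = "conventional")
  expect_gt(max(abs(bilateral_filter(s * img, p_conv) -
                      s * bilateral_filter(img, p_conv))), 1e-6)
})

test_that("iteration feeds each pass the previous output", {
  img <- random_image(12, 12, 30)
  p1 <- bilateral_params(sigma_d = 1.5, sigma_r = 0.3, half_width = 2)
  p3 <- bilateral_params(sigma_d = 1.5, sigma_r = 0.3, half_width = 2,
                         iterations = 3)
  once <- bilateral_filter(img, p1)
  expect_equal(bilateral_filter(img, p1, keep_intermediate = TRUE),
               once, ignore_attr = "snapshots")
  out3 <- bilateral_filter(img, p3, keep_intermediate = TRUE)
  snaps <- attr(out3, "snapshots")
  expect_length(snaps, 3)
  expect_equal(snaps[[1]], once, tolerance = 1e-14)
  expect_equal(snaps[[2]], bilateral_filter(once, p1), tolerance = 1e-13)
  expect_equal(snaps[[3]], out3, ignore_attr = "snapshots")
})

test_that("normalized filtering equalizes relative residuals across brightness", {
  # two-level phantom with identical relative (multiplicative) noise: the
  # normalized filter should leave comparable relative residuals in both
  # regions, the conventional filter a clearly larger one in the bright region
  spec <- phantom_spec(canvas = c(64, 64), background = 0.2,
                       shapes = list(shape_rectangle(c(1, 33), c(64, 32), 0.8)))
  clean <- generate_phantom(spec)
  dark_cols <- 5:20; bright_cols <- 45:60  # away from the edge and borders
  ratios <- sapply(1:10, function(seed) {
    noisy <- apply_speckle(clean, speckle_params(variance = 0.075),
                           seed = seed)
    sapply(c("normalized", "conventional"), function(mode) {
      filt <- bilateral_filter(noisy, bilateral_params(
        sigma_d = 3, sigma_r = 0.15, mode = mode, iterations = 5))
      resid <- filt - clean
      rel_bright <- sd(resid[10:55, bright_cols]) / 0.8
      rel_dark <- sd(resid[10:55, dark_cols]) / 0.2
      rel_bright / rel_dark
    })
  })
  # normalized: bright/dark relative residuals agree within 20% on average
  expect_lt(abs(mean(ratios["normalized", ]) - 1), 0.2)
  # conventional: systematically larger relative residual in the bright region
  expect_gt(mean(ratios["conventional", ]), mean(ratios["normalized", ]))
  expect_gt(mean(ratios["conventional", ]), 1.2)
})

test_that("iterating the normalized filter keeps improving NMSE on the phantom", {
  # at a moderate range width a single pass under-smooths; feeding the
  # output back four more times cuts the NMSE severalfold
  clean <- generate_phantom(default_phantom_spec())
  noisy <- apply_speckle(clean, speckle_params(variance = 0.075), seed = 2)
  p1 <- bilateral_params(sigma_d = 3, sigma_r = 0.2, mode = "normalized")
  p5 <- bilateral_params(sigma_d = 3, sigma_r = 0.2, mode = "normalized",
                         iterations = 5)
  expect_lt(nmse(clean, bilateral_filter(noisy, p5)),
            nmse(clean, bilateral_filter(noisy, p1)))
})

test_that("parameter validation refuses degenerate settings", {
  expect_error(bilateral_params(sigma_d = 0), "sigma_d")
  expect_error(bilateral_params(sigma_r = -1), "sigma_r")
  expect_error(bilateral_params(iterations = 0), "iterations")
  expect_error(bilateral_params(half_width = 0), "half_width")
  img <- matrix(0.5, 8, 8)
  expect_error(
    bilateral_filter(img, bilateral_params(sigma_d = 3, half_width = 9)),
    "half_width")
})
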