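test_that("NMSE closed forms and mean-removal property hold", {
  ref <- random_image(6, 6, 1)
  expect_equal(nmse(ref, ref), 0)
  # a constant offset is absorbed by the means
  expect_equal(nmse(ref, ref + 0.1), 0, tolerance = 1e-12)
  # independent oracle through stats::var of the centred difference
  test <- random_image(6, 6, 2)
  expect_equal(nmse(ref, test),
               var(as.vector(ref - test)) / var(as.vector(ref)),
               tolerance = 1e-12)
  expect_error(nmse(matrix(0.5, 4, 4), test[1:4, 1:4]), "constant")
  expect_error(nmse(ref, test[1:4, 1:4]), "dimensions")
})

test_that("alpha is the Pearson correlation of the pixel intensities", {
  ref <- random_image(5, 7, 3)
  test <- random_image(5, 7, 4)
  expect_equal(noise_suppression_alpha(ref, ref), 1)
  expect_equal(noise_suppression_alpha(ref, -ref), -1)
  # invariant under positive affine maps of the test image
  expect_equal(noise_suppression_alpha(ref, 0.3 * ref + 0.2), 1,
               tolerance = 1e-12)
  expect_equal(noise_suppression_alpha(ref, test),
               cor(as.vector(ref), as.vector(test)), tolerance = 1e-12)
  expect_error(noise_suppression_alpha(ref, matrix(0.2, 5, 7)), "constant")
})

test_that("beta correlates the 4-neighbour Laplacians of the two images", {
  ref <- random_image(5, 5, 5)
  test <- random_image(5, 5, 6)
  expect_equal(edge_preservation_beta(ref, ref), 1)
  # explicit scalar oracle: build both interior Laplacians by hand
  lap <- function(m) {
    out <- matrix(NA_real_, 3, 3)
    for (r in 2:4) for (c in 2:4) {
      out[r - 1, c - 1] <- 4 * m[r, c] -
        m[r - 1, c] - m[r + 1, c] - m[r, c - 1] - m[r, c + 1]
    }
    out
  }
  expect_equal(edge_preservation_beta(ref, test),
               cor(as.vector(lap(ref)), as.vector(lap(test))),
               tolerance = 1e-12)
  expect_error(edge_preservation_beta(matrix(0.2, 5, 5), test), "Laplacian")
})

test_that("beta degrades monotonically with blur on a step edge", {
  img <- matrix(0.1, 32, 32); img[, 17:32] <- 0.9
  mild <- gaussian_filter(img, 1, 7)
  heavy <- gaussian_filter(img, 4, 25)
  b_mild <- edge_preservation_beta(img, mild)
  b_heavy <- edge_preservation_beta(img, heavy)
  expect_gt(b_mild, b_heavy)
  expect_gt(b_mild, 0.5)
})

test_that("image metrics are invariant under simultaneous flips", {
  ref <- random_image(8, 9, 7)
  test <- random_image(8, 9, 8)
  fl <- function(m) m[nrow(m):1, ncol(m):1]
  expect_equal(nmse(fl(ref), fl(test)), nmse(ref, test), tolerance = 1e-12)
  expect_equal(noise_suppression_alpha(fl(ref), fl(test)),
               noise_suppression_alpha(ref, test), tolerance = 1e-12)
  expect_equal(edge_preservation_beta(fl(ref), fl(test)),
               edge_preservation_beta(ref, test), tolerance = 1e-12)
})

test_that("Laplacian contrast stencil arithmetic is exact", {
  expect_equal(laplacian_contrast(matrix(0.4, 8, 8),
                                  data.frame(row = 3:5, col = 3:5)), 0)
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  expect_equal(laplacian_contrast(img, data.frame(row = 5, col = 5)), 4)
  # the 4 neighbours each see |-1|
  expect_equal(laplacian_contrast(img, data.frame(row = c(4, 6, 5, 5),
                                                  col = c(5, 5, 4, 6))), 1)
  expect_error(laplacian_contrast(img, data.frame(row = c(3, 1), col = c(3, 5))),
               "2")
  expect_error(laplacian_contrast(img, data.frame(row = numeric(0),
                                                  col = numeric(0))),
               "at least one")
})

test_that("Pratt FOM closed forms, asymmetry and over-segmentation penalty", {
  b <- tibble::tibble(row = c(3, 3, 4, 5), col = c(3, 4, 5, 5))
  expect_equal(pratt_fom(b, b), 1)
  # one pixel offset at gamma = 0.05
  expect_equal(pratt_fom(tibble::tibble(row = 1, col = 2),
                         tibble::tibble(row = 1, col = 1)),
               1 / 1.05, tolerance = 1e-9)
  expect_equal(1 / 1.05, 0.952381, tolerance = 1e-6)
  # spurious far detections halve the score via max(I_A, I_I)
  ref <- tibble::tibble(row = rep(1, 100), col = 1:100)
  auto <- dplyr::bind_rows(ref, tibble::tibble(row = rep(500, 100), col = 1:100))
  expect_lte(pratt_fom(auto, ref), 0.5)
  # the distance sum runs from reference pixels to the auto set: swapping
  # the arguments changes the value (only the normalization is symmetric)
  a <- tibble::tibble(row = c(1, 1), col = c(1, 9))
  r <- tibble::tibble(row = c(1, 1), col = c(1, 2))
  expect_false(isTRUE(all.equal(pratt_fom(a, r), pratt_fom(r, a))))
  expect_error(pratt_fom(a, r, gamma = 0), "gamma")
})

test_that("filtering improves NMSE over the corrupted phantom", {
  clean <- generate_phantom(default_phantom_spec())
  noisy <- apply_speckle(clean, speckle_params(variance = 0.075), seed = 6)
  base <- nmse(clean, noisy)
  for (cfg in list(c("conventional", 0.2), c("normalized", 0.5),
                   c("normalized", 0.8), c("conventional", 0.8))) {
    filt <- bilateral_filter(noisy, bilateral_params(
      sigma_d = 3, sigma_r = as.numeric(cfg[2]), mode = cfg[1]))
    expect_lt(nmse(clean, filt), base)
  }
})

test_that("metrics_report bundles the three measures consistently", {
  ref <- random_image(8, 8, 10)
  test <- random_image(8, 8, 11)
  rep <- metrics_report(ref, test)
  expect_named(rep, c("nmse", "alpha", "beta"))
  expect_equal(rep$nmse, nmse(ref, test))
  expect_equal(rep$alpha, noise_suppression_alpha(ref, test))
  expect_equal(rep$beta, edge_preservation_beta(ref, test))
})
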