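# follikel

Speckle-reducing bilateral filtering and B-spline snake segmentation for
2-D ultrasound images, built for the measurement of ovarian follicles in
cattle reproduction studies.

Ultrasound speckle is multiplicative: the observed image is modelled as
`J(X) = I(X) * (1 + eta(X))` with zero-mean perturbations `eta`, so noise
amplitude scales with local brightness. A conventional Gaussian bilateral
filter weights each neighbour by

```
w(Y) = exp(-||X - Y||^2 / (2 sigma_d^2)) * exp(-|J(Y) - J(X)|^2 / (2 sigma_r^2))
```

and therefore cannot serve bright and dark regions with a single range
width `sigma_r`: the intensity difference between two pixels of one
homogeneous region is proportional to the region's brightness. The filter
implemented here replaces the range distance by its centre-normalized form

```
D(X, Y) = |J(Y) - J(X)| / max(|J(X)|, epsilon)
```

which under the multiplicative model depends only on the noise, not on the
region's intensity, so one `sigma_r` (now in relative-intensity units)
despeckles bright and dark regions alike. Both filters can be iterated,
feeding each pass's output back as input.

Around the filter the package provides:

* a piecewise-constant **phantom generator** (circles and rectangles at two
  foreground levels on a darker background) and a seeded multiplicative
  **speckle simulator**;
* **quality metrics**: NMSE, noise-suppression `alpha` (mean-removed
  normalized cross-correlation of intensities), edge-preservation `beta`
  (the same on 4-neighbour Laplacians), Laplacian local contrast over a
  point set, and Pratt's figure of merit for boundary accuracy;
* a closed cubic **B-spline snake** driven by a generalized gradient vector
  flow (GVF) field, initialized as a circle inside the target follicle,
  for boundary extraction;
* experiment runners: `run_sweep()` (the `sigma_r` sweep with per-mode
  optimal points) and `run_pipeline()` (filter, segment, score), plus
  PNG/TIFF/PGM image and CSV boundary I/O and a small command-line wrapper
  in `inst/scripts/follikel.R`.

## Worked example

```r
library(follikel)

clean <- generate_phantom(default_phantom_spec())          # 256 x 256
noisy <- apply_speckle(clean, speckle_params(variance = 0.075), seed = 1)

filt <- bilateral_filter(noisy, bilateral_params(
  sigma_d = 3, sigma_r = 0.7, mode = "normalized", iterations = 5))
metrics_report(clean, filt)
#> # A tibble: 1 x 3
#>    nmse alpha  beta
#>   <dbl> <dbl> <dbl>
#> 1 0.195 0.932 0.854
```

At this wide range setting the NMSE (0.195) sits slightly above the
corrupted image's 0.156: five iterations trade some large-scale fidelity
for a dramatically cleaner edge structure — `beta` is 0.854 against 0.042
for the conventional filter at identical settings, and the residual
Laplacian contrast in homogeneous regions falls below 0.003 (speckled:
0.63). At the normalized filter's own NMSE optimum (`sigma_r` = 0.2) the
NMSE falls to 0.012 with `beta` = 0.94.

Segmentation of a speckled follicle phantom:

```r
foll <- generate_phantom(follicle_phantom_spec())          # two dark follicles
noisy <- apply_speckle(foll, speckle_params(variance = 0.075), seed = 1)
rec <- run_pipeline(noisy, init_center = c(64, 56), init_radius = 10,
                    mode = "normalized", sigma_r = 0.3,
                    reference = boundary_pixels(
                      outer((1:128 - 64)^2, (1:128 - 56)^2, "+") <= 20^2))
rec$fom
#> [1] 0.995
```

A figure of merit of 0.995 means the extracted boundary lies essentially on
the true follicle wall; segmenting the unfiltered image instead drops it
to 0.65 as speckle-induced edges capture the contour.

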