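# Small cohort configurations used across tests. The tiny config keeps the
# full default structure layout but only a handful of subjects, so disk
# round trips stay fast.
tiny_config <- function(n = 2L, seed = 11L, ...) {
  cohort_config(n_per_group = c(CTRL = n, earlyPD = n, latePD = n),
                seed = seed, ...)
}

# Continuous-intensity random ROI on a small grid (for affine-invariance and
# volumetry checks).
random_intensity_roi <- function(dims = c(7, 7, 4), fill = 0.75) {
  img <- array(stats::rnorm(prod(dims), 100, 10), dims)
  mask <- array(stats::runif(prod(dims)) < fill, dims)
  mask[1:3, 1, 1] <- TRUE
  list(image = img, mask = mask)
}
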