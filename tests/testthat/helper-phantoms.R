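# Small, fast phantom specs shared across tests.

# uniform membrane ring, single panchromatic page
small_ring_spec <- function(radius_nm = 1200, psf_fwhm_nm = 80,
                            pixel_size_nm = 20, image_px = 180,
                            brightness = 100, noise = "none", seed = NULL,
                            membrane_width_nm = 8) {
  ctr <- (image_px - 1) / 2
  phantom_spec(
    image_size_px = c(image_px, image_px),
    pixel_size_nm = pixel_size_nm,
    vesicle = list(center_px = c(ctr, ctr), radius_nm = radius_nm),
    membrane_width_nm = membrane_width_nm,
    paints = list(membrane = phase_paint(channel_fraction_1 = 1,
                                         brightness = brightness)),
    detection_bands_nm = NULL, psf_fwhm_nm = psf_fwhm_nm,
    noise = noise, seed = seed)
}

# two-band ring with a single channel fraction everywhere
gp_ring_spec <- function(fraction, noise = "none", seed = NULL,
                         brightness = 100) {
  ctr <- (120 - 1) / 2
  phantom_spec(
    image_size_px = c(120, 120), pixel_size_nm = 20,
    vesicle = list(center_px = c(ctr, ctr), radius_nm = 800),
    paints = list(membrane = phase_paint(channel_fraction_1 = fraction,
                                         brightness = brightness)),
    psf_fwhm_nm = 80, noise = noise, seed = seed)
}

# analytic Gaussian ridge image: vertical ridge at column x0 (0-based coords)
gaussian_ridge <- function(h = 60, w = 60, x0 = 29.5, sigma = 4,
                           amplitude = 100, offset = 0) {
  xs <- 0:(w - 1)
  row <- offset + amplitude * exp(-(xs - x0)^2 / (2 * sigma^2))
  matrix(rep(row, each = h), h, w)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
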