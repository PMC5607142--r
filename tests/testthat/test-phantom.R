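test_that("band_fractions matches high-resolution quadrature", {
  model <- emission_model(595, 30)
  bands <- list(c(520, 570), c(620, 700))
  got <- band_fractions(model, bands)
  # independent oracle: midpoint quadrature of the Gaussian line shape
  quad <- vapply(bands, function(b) {
    wl <- seq(b[1L] + 0.005, b[2L] - 0.005, by = 0.01)
    sum(exp(-(wl - 595)^2 / (2 * 30^2))) * 0.01 / (sqrt(2 * pi) * 30)
  }, numeric(1))
  expect_equal(got, quad, tolerance = 1e-6)
  expect_true(all(got >= 0 & got <= 1) && sum(got) <= 1)
})

test_that("a zero-width spectrum is a delta line", {
  bands <- list(c(520, 570), c(620, 700))
  expect_equal(band_fractions(emission_model(545, 0), bands), c(1, 0))
  expect_equal(band_fractions(emission_model(660, 0), bands), c(0, 1))
  expect_error(band_fractions(emission_model(545, 25), list(c(570, 520))),
               "low < high")
  expect_error(
    band_fractions(emission_model(545, 25), list(c(520, 600), c(590, 700))),
    "overlap")
})

test_that("symmetric channel split renders identical band images", {
  ph <- render_phantom(gp_ring_spec(0.5))
  expect_identical(ph$stack$pages[[1L]], ph$stack$pages[[2L]])
})

test_that("noise-free GP on the membrane equals 2f - 1 by pixel arithmetic", {
  ph <- render_phantom(gp_ring_spec(0.405))
  i1 <- ph$stack$pages[[1L]]; i2 <- ph$stack$pages[[2L]]
  on_mem <- (i1 + i2) > 0.1 * max(i1 + i2)
  gp <- (i1[on_mem] - i2[on_mem]) / (i1[on_mem] + i2[on_mem])
  expect_equal(gp, rep(-0.19, sum(on_mem)), tolerance = 1e-12)
  expect_equal(unname(ph$truth$gp_true["membrane"]), -0.19)
})

test_that("rendering is linear in brightness", {
  p1 <- render_phantom(small_ring_spec(brightness = 50))$stack$pages[[1L]]
  p2 <- render_phantom(small_ring_spec(brightness = 100))$stack$pages[[1L]]
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("noise-free photon count is conserved through PSF and binning", {
  r_nm <- 1200; b <- 80
  ph <- render_phantom(small_ring_spec(radius_nm = r_nm, brightness = b))
  total <- sum(ph$stack$pages[[1L]])
  expect_rel_equal(total, b * 2 * pi * r_nm, 5e-3)
})

test_that("bleach series follows geometric decay in expectation", {
  spec <- small_ring_spec(noise = "none")
  spec$bleach_survival_per_frame <- 0.5
  spec$n_frames <- 3L
  ph <- render_bleach_series(spec)
  m <- vapply(ph$stack$pages, mean, numeric(1))
  expect_equal(m / m[1L], c(1, 0.5, 0.25), tolerance = 1e-12)
  spec$bleach_survival_per_frame <- 0.9875
  spec$n_frames <- 20L
  ph <- render_bleach_series(spec)
  m <- vapply(ph$stack$pages, mean, numeric(1))
  expect_equal(m[20L] / m[1L], 0.9875^19, tolerance = 1e-12)
  # survival 1: all frames identical
  spec$bleach_survival_per_frame <- 1
  spec$n_frames <- 2L
  ph <- render_bleach_series(spec)
  expect_identical(ph$stack$pages[[1L]], ph$stack$pages[[2L]])
})

test_that("identical spec and seed give bit-identical noisy output", {
  a <- render_phantom(gp_ring_spec(0.54, noise = "poisson", seed = 42))
  b <- render_phantom(gp_ring_spec(0.54, noise = "poisson", seed = 42))
  expect_identical(a$stack$pages, b$stack$pages)
  c2 <- render_phantom(gp_ring_spec(0.54, noise = "poisson", seed = 43))
  expect_false(identical(a$stack$pages, c2$stack$pages))
  # replicate renderer agrees with the one-shot renderer at the same seed
  reps <- render_phantom_replicates(gp_ring_spec(0.54, noise = "poisson"),
                                    seeds = c(42, 43))
  expect_identical(reps$stacks[[1L]]$pages, a$stack$pages)
  expect_identical(reps$stacks[[2L]]$pages, c2$stack$pages)
})

test_that("phantom spec validation catches inconsistent geometry", {
  ctr <- 59.5
  expect_error(phantom_spec(
    image_size_px = c(120, 120),
    vesicle = list(center_px = c(ctr, ctr), radius_nm = 800),
    paints = list(a = phase_paint(channel_fraction_1 = 0.5),
                  b = phase_paint(channel_fraction_1 = 0.2)),
    phases = list(list(start_deg = 0, end_deg = 180, paint = "a"),
                  list(start_deg = 90, end_deg = 360, paint = "b")),
    psf_fwhm_nm = 80), "full circle")
  expect_error(phantom_spec(
    image_size_px = c(120, 120), membrane_width_nm = 100, psf_fwhm_nm = 80,
    paints = list(a = phase_paint(channel_fraction_1 = 0.5))),
    "sub-resolution")
  expect_error(phase_paint(), "exactly one")
  expect_error(phase_paint(channel_fraction_1 = 1.2), "0, 1")
  expect_error(phantom_spec(
    image_size_px = c(120, 120),
    vesicle = list(center_px = c(ctr, ctr), radius_nm = 800),
    paints = list(a = phase_paint(channel_fraction_1 = 0.5)),
    lambda_windows_nm = c(513, 693), psf_fwhm_nm = 80),
    "spectrum")
})

test_that("phantom ROI set carries the true contour and per-region ROIs", {
  ph <- render_phantom(phantom_preset("fig5-nanodomain", noise = "none"))
  expect_setequal(names(ph$rois$rois), c("contour", "domain", "surround"))
  expect_true(ph$rois$rois$contour$closed)
  expect_equal(unname(ph$truth$gp_true),
               unname(c(2 * 0.405 - 1, 2 * 0.540 - 1)))
})
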