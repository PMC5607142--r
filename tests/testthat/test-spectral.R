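# 9-nm window axis starting at 513 nm, as used by the lambda-stack presets
lambda_axis <- function(n = 20, start = 513) {
  lapply(seq_len(n) - 1L, function(i) c(start + 9 * i, start + 9 * (i + 1)))
}

stack_from_values <- function(vals, h = 6, w = 6) {
  image_stack(lapply(vals, function(v) matrix(v, h, w)),
              axis_kind = "wavelength", band_edges_nm = lambda_axis(length(vals)))
}

trace_from_values <- function(vals, n = length(vals)) {
  structure(list(
    wavelengths_nm = vapply(lambda_axis(n), mean, numeric(1)),
    intensities = vals, normalized = FALSE), class = "spectrum_trace")
}

test_that("ROI spectra are per-window means with optional normalization", {
  st <- stack_from_values(rep(4.2, 5))
  roi <- roi_circle(c(2.5, 2.5), 2)
  raw <- extract_spectrum(st, roi, normalize = FALSE)
  expect_equal(raw$intensities, rep(4.2, 5))
  norm <- extract_spectrum(st, roi, normalize = TRUE)
  expect_equal(norm$intensities, rep(1, 5))
  expect_error(extract_spectrum(st, roi_circle(c(50, 50), 1)), "no pixels")
})

test_that("normalization is idempotent", {
  tr <- trace_from_values(c(1, 5, 3, 2))
  once <- normalize_spectrum(tr)
  twice <- normalize_spectrum(once)
  expect_identical(once$intensities, twice$intensities)
  expect_equal(max(once$intensities), 1)
})

test_that("peak estimation: argmax bin, parabolic refinement, edge fallback", {
  # single nonzero window
  v <- rep(0, 20); v[10] <- 1 # window 594-603, center 598.5
  tr <- trace_from_values(v)
  expect_equal(peak_wavelength(tr, "argmax_bin")$peak_nm, 598.5)
  # symmetric triplet peaks exactly at the central window center
  v <- rep(0, 20); v[9:11] <- c(0.5, 1, 0.5)
  expect_equal(peak_wavelength(trace_from_values(v), "parabolic")$peak_nm,
               598.5)
  # maximum at the axis edge: parabolic falls back to the bin center
  v <- 20:1
  expect_equal(peak_wavelength(trace_from_values(v), "parabolic")$peak_nm,
               517.5)
  expect_error(peak_wavelength(trace_from_values(rep(0, 20))), "no peak")
})

test_that("parabolic peak of a binned Gaussian lands within 1 nm of truth", {
  axis <- lambda_axis(20)
  centers <- vapply(axis, mean, numeric(1))
  for (true_peak in c(600, 570.3, 610.8)) {
    v <- vapply(axis, function(b)
      stats::pnorm(b[2], true_peak, 25) - stats::pnorm(b[1], true_peak, 25),
      numeric(1))
    est <- peak_wavelength(trace_from_values(v), "parabolic")$peak_nm
    expect_lt(abs(est - true_peak), 1)
  }
})

test_that("peak shift is disordered minus ordered and needs a shared axis", {
  o <- trace_from_values(exp(-(seq(517.5, 688.5, by = 9) - 570)^2 / 1250))
  d <- trace_from_values(exp(-(seq(517.5, 688.5, by = 9) - 610)^2 / 1250))
  expect_equal(peak_shift(o, o), 0)
  expect_equal(peak_shift(o, d), 40, tolerance = 0.02)
  short <- trace_from_values(rep(1, 5))
  expect_error(peak_shift(o, short), "different wavelength axes")
})

test_that("spectral-shift recovery across true separations of 10/30/50 nm", {
  base <- phantom_preset("spectra-shift", noise = "none")
  for (delta in c(10, 30, 50)) {
    spec <- base
    spec$paints$ordered$spectrum <- emission_model(580, 25)
    spec$paints$disordered$spectrum <- emission_model(580 + delta, 25)
    ph <- render_phantom(spec)
    o <- extract_spectrum(ph$stack, ph$rois$rois$ordered)
    d <- extract_spectrum(ph$stack, ph$rois$rois$disordered)
    expect_lt(abs(peak_shift(o, d) - delta), 2)
  }
})

test_that("ordered/disordered intensity ratio crosses unity once", {
  ph <- render_phantom(phantom_preset("spectra-shift", noise = "none"))
  ratio <- channel_intensity_ratio(ph$stack, ph$rois$rois$ordered,
                                   ph$rois$rois$disordered)
  ok <- !ratio$excluded
  expect_gt(ratio$ratio[ok][1L], 1)            # blue windows
  expect_lt(ratio$ratio[ok][sum(ok)], 1)       # red windows
  expect_equal(sum(diff(ratio$ratio[ok] > 1) != 0), 1L) # single crossing
  # identical ROIs give ratio 1 everywhere; doubled brightness gives 2
  same <- channel_intensity_ratio(ph$stack, ph$rois$rois$ordered,
                                  ph$rois$rois$ordered)
  expect_equal(same$ratio[!same$excluded],
               rep(1, sum(!same$excluded)))
})

test_that("band recombination partitions the total intensity exactly", {
  set.seed(4)
  vals <- lapply(1:6, function(i) matrix(rpois(36, 30), 6, 6))
  st <- image_stack(vals, axis_kind = "wavelength",
                    band_edges_nm = lambda_axis(6))
  lo <- c(513, 540); hi <- c(540, 567)
  rc <- recombine_bands(st, lo, hi)
  expect_equal(rc$pages[[1L]] + rc$pages[[2L]], Reduce(`+`, vals))
  # identical bands give identical channels
  same <- recombine_bands(st, lo, lo)
  expect_identical(same$pages[[1L]], same$pages[[2L]])
  expect_error(recombine_bands(st, c(100, 110), hi), "no windows")
})

test_that("a second emitter in the lumen separates into the blue band", {
  spec <- phantom_preset("spectra-shift", noise = "none")
  spec$paints$gfp <- phase_paint(spectrum = emission_model(510, 15),
                                 brightness = 0.02)
  ctr <- (280 - 1) / 2
  spec$extra_objects <- list(list(center_px = c(ctr, ctr),
                                  diameter_nm = 3000, paint = "gfp"))
  ph <- render_phantom(spec)
  rc <- recombine_bands(ph$stack, c(500, 530), c(570, 691))
  lumen <- roi_pixel_mask(roi_circle(c(ctr, ctr), 40), dim(rc$pages[[1L]]))
  membrane <- roi_pixel_mask(ph$rois$rois$ordered, dim(rc$pages[[1L]]))
  expect_gt(mean(rc$pages[[1L]][lumen]), 10 * mean(rc$pages[[2L]][lumen]))
  expect_gt(mean(rc$pages[[2L]][membrane]), 5 * mean(rc$pages[[1L]][membrane]))
})
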