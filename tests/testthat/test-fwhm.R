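test_that("contour resampling places anchors at arc-length multiples", {
  seg <- roi_polyline(cbind(c(0, 30), c(5, 5)))
  rs <- resample_contour(seg, 3)
  expect_equal(nrow(rs$anchors), 11L)
  expect_equal(rs$anchors[, "x"], seq(0, 30, by = 3))
  expect_equal(rs$anchors[, "y"], rep(5, 11))
  expect_equal(rs$tangents, cbind(rep(1, 11), rep(0, 11)), ignore_attr = TRUE)
})

test_that("closed square resampled at quarter-perimeter hits the corners", {
  sq <- roi_polyline(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), closed = TRUE)
  rs <- resample_contour(sq, 10)
  expect_equal(nrow(rs$anchors), 4L)
  expect_equal(rs$anchors[, "x"], c(0, 10, 10, 0), ignore_attr = TRUE)
  # tangents at the corners are the 45-degree corner bisectors and rotate 90
  # degrees between consecutive corners
  for (i in 1:4) {
    a <- rs$tangents[i, ]; b <- rs$tangents[i %% 4 + 1, ]
    expect_equal(sum(a * b), 0, tolerance = 1e-12)
  }
})

test_that("circle tangents are orthogonal to the radius within 1 degree", {
  ang <- seq(0, 2 * pi, length.out = 629)[-629]
  circ <- roi_polyline(cbind(150 + 100 * cos(ang), 150 + 100 * sin(ang)),
                       closed = TRUE)
  rs <- resample_contour(circ, 3)
  radial <- rs$anchors - matrix(rep(c(150, 150), each = nrow(rs$anchors)),
                                ncol = 2)
  radial <- radial / sqrt(rowSums(radial^2))
  dot <- abs(rowSums(radial * rs$tangents))
  expect_true(all(dot < sin(1 * pi / 180)))
})

test_that("profiles sample the image by bilinear interpolation", {
  const <- matrix(7, 50, 50)
  pr <- extract_profile(const, c(25, 25), c(1, 0))
  expect_false(pr$rejected)
  expect_equal(pr$intensities, rep(7, 41))
  expect_equal(pr$positions, seq(-20, 20))
  # analytic Gaussian ridge, horizontal normal: at half-pixel sampling
  # offsets bilinear interpolation is exactly the two-column average, and
  # within interpolation tolerance of the ideal ridge profile
  img <- gaussian_ridge(x0 = 24.5, sigma = 4)
  pr <- extract_profile(img, c(24.5, 30), c(1, 0))
  g <- function(x) 100 * exp(-x^2 / (2 * 16))
  expect_equal(pr$intensities, (g(pr$positions - 0.5) + g(pr$positions + 0.5)) / 2,
               tolerance = 1e-12)
  expect_lt(max(abs(pr$intensities - g(pr$positions))), 1) # 1% of amplitude
  # profile leaving the image is rejected, not an error
  pr <- extract_profile(const, c(5, 25), c(1, 0))
  expect_true(pr$rejected)
})

test_that("gaussian fit recovers noiseless parameters to 1e-6", {
  x <- seq(-20, 20)
  y <- 10 + 100 * exp(-x^2 / (2 * 25))
  pr <- structure(list(positions = x, intensities = y, rejected = FALSE),
                  class = "line_profile")
  fit <- fit_gaussian_profile(pr)
  expect_true(fit$converged)
  expect_equal(fit$offset, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$center_px, 0, tolerance = 1e-6)
  expect_equal(fit$sigma_px, 5, tolerance = 1e-6)
  expect_equal(fit$fwhm_px, 2 * sqrt(2 * log(2)) * 5, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["sigma_px"]]), fit$sigma_px)
})

test_that("flat and off-center bimodal profiles are rejected", {
  x <- seq(-20, 20)
  flat <- structure(list(positions = x, intensities = rep(3, 41),
                         rejected = FALSE), class = "line_profile")
  expect_false(fit_gaussian_profile(flat)$converged)
  # two membranes in the window: the fit either locks on a far off-center
  # peak or spreads across both; both violate the acceptance rules
  bimod <- structure(list(
    positions = x,
    intensities = 100 * exp(-(x - 14)^2 / 8) + 100 * exp(-(x + 14)^2 / 8),
    rejected = FALSE), class = "line_profile")
  expect_false(fit_gaussian_profile(bimod)$converged)
  rej <- structure(list(positions = x, intensities = rep(NA_real_, 41),
                        rejected = TRUE), class = "line_profile")
  expect_false(fit_gaussian_profile(rej)$converged)
})

test_that("fitted FWHM matches the closed form on analytic ridges to <0.1%", {
  # ridge centered on a pixel column so the samples hit pixel centers
  # exactly and the check isolates the fit from interpolation
  for (sigma in c(2, 4, 8)) {
    img <- gaussian_ridge(h = 60, w = 80, x0 = 40, sigma = sigma)
    pr <- extract_profile(img, c(40, 30), c(1, 0))
    fit <- fit_gaussian_profile(pr)
    expect_true(fit$converged)
    expect_rel_equal(fit$fwhm_px, 2 * sqrt(2 * log(2)) * sigma, 1e-3)
  }
})

test_that("summaries pool converged fits and convert to nm", {
  mkfit <- function(fwhm_px, conv = TRUE) structure(
    list(fwhm_px = fwhm_px, converged = conv), class = "gaussian_fit")
  sm <- summarize_fwhm(list(mkfit(4), mkfit(4), mkfit(4)), 20)
  expect_equal(sm$mean_fwhm_nm, 80)
  expect_equal(sm$sd_fwhm_nm, 0)
  sm <- summarize_fwhm(list(mkfit(4), mkfit(NA, FALSE)), 20)
  expect_equal(sm$mean_fwhm_nm, 80)
  expect_equal(sm$n_profiles_used, 1L)
  expect_equal(sm$n_rejected, 1L)
  expect_error(summarize_fwhm(list(mkfit(NA, FALSE)), 20), "no valid profiles")
  # per-image aggregation
  sm <- summarize_fwhm(list(mkfit(4), mkfit(6), mkfit(5)), 20,
                       image = c(1, 1, 2))
  expect_equal(sm$mean_of_image_means_nm, mean(c(100, 100)))
})

test_that("resolution ratio divides confocal by STED means", {
  mk <- function(m, s) structure(list(mean_fwhm_nm = m, sd_fwhm_nm = s),
                                 class = "fwhm_summary")
  expect_equal(resolution_ratio(mk(240, 0), mk(80, 0))$ratio, 3)
  expect_equal(resolution_ratio(mk(100, 5), mk(100, 5))$ratio, 1)
  expect_error(resolution_ratio(mk(240, 0), mk(0, 0)), "zero")
  r <- resolution_ratio(mk(200, 20), mk(100, 5))
  expect_equal(r$sd, 2 * sqrt(0.01 + 0.0025))
})

test_that("noise-free phantom recovery is within 2% at fine sampling", {
  # membrane (8 nm) below the pixel (10 nm), both far below the PSF
  spec <- small_ring_spec(radius_nm = 800, psf_fwhm_nm = 80,
                          pixel_size_nm = 10, image_px = 220)
  ph <- render_phantom(spec)
  fits <- profile_image_fwhm(ph$stack$pages[[1L]], ph$truth$contour)
  sm <- summarize_fwhm(fits, 10)
  expect_rel_equal(sm$mean_fwhm_nm, 80, 0.02)
})

test_that("measured FWHM is nondecreasing in the phantom PSF width", {
  means <- vapply(c(80, 120, 240), function(psf) {
    ph <- render_phantom(small_ring_spec(psf_fwhm_nm = psf))
    sm <- summarize_fwhm(
      profile_image_fwhm(ph$stack$pages[[1L]], ph$truth$contour), 20)
    sm$mean_fwhm_nm
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("mean FWHM is invariant to contour rotation within 2%", {
  ph <- render_phantom(small_ring_spec())
  base <- summarize_fwhm(
    profile_image_fwhm(ph$stack$pages[[1L]], ph$truth$contour), 20)
  v <- ph$truth$contour$vertices
  ctr <- c(mean(v[, 1L]), mean(v[, 2L]))
  a <- 37 * pi / 180
  rot <- cbind(ctr[1L] + cos(a) * (v[, 1L] - ctr[1L]) -
                 sin(a) * (v[, 2L] - ctr[2L]),
               ctr[2L] + sin(a) * (v[, 1L] - ctr[1L]) +
                 cos(a) * (v[, 2L] - ctr[2L]))
  turned <- summarize_fwhm(
    profile_image_fwhm(ph$stack$pages[[1L]],
                       roi_polyline(rot, closed = TRUE)), 20)
  expect_rel_equal(turned$mean_fwhm_nm, base$mean_fwhm_nm, 0.02)
})
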