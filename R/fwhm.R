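#' Resample a membrane contour at regular arc-length intervals
#'
#' Walks the polyline and places anchor points at arc-length multiples of
#' `spacing_px` starting from the first vertex (the final partial interval is
#' dropped; for a closed contour the walk includes the closing segment). The
#' local tangent at each anchor is the central difference across its
#' neighboring anchors (one-sided at open-contour ends, wrapped for closed
#' contours), which is what the perpendicular profile direction is derived
#' from.
#'
#' @param contour a [roi_polyline()].
#' @param spacing_px anchor spacing along the contour, pixels (default 3).
#' @return A list with `anchors` (n x 2 matrix of `(x, y)`), `tangents`
#'   (n x 2 matrix of unit vectors) and `normals` (tangents rotated +90°).
#' @export
resample_contour <- function(contour, spacing_px = 3) {
  stopifnot(inherits(contour, "roi_polyline"), spacing_px > 0)
  v <- contour$vertices
  if (contour$closed) v <- rbind(v, v[1L, , drop = FALSE])
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total <= 0) stop("contour has zero length")
  s <- seq(0, total, by = spacing_px)
  # interpolate x and y against arc length
  ax <- stats::approx(cum, v[, 1L], xout = s, ties = "ordered")$y
  ay <- stats::approx(cum, v[, 2L], xout = s, ties = "ordered")$y
  anchors <- cbind(x = ax, y = ay)
  if (contour$closed && total - s[length(s)] < 1e-9)
    anchors <- anchors[-nrow(anchors), , drop = FALSE] # s = total == start
  n <- nrow(anchors)
  if (n < 2L) stop("contour shorter than one spacing interval")
  idx_prev <- if (contour$closed) c(n, seq_len(n - 1L)) else c(1L, seq_len(n - 1L))
  idx_next <- if (contour$closed) c(seq_len(n)[-1L], 1L) else c(seq_len(n)[-1L], n)
  tg <- anchors[idx_next, , drop = FALSE] - anchors[idx_prev, , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  list(anchors = anchors, tangents = tg,
       normals = cbind(-tg[, 2L], tg[, 1L]))
}

#' Profile sampling parameters
#'
#' @param spacing_px anchor spacing along the contour (default 3 px).
#' @param profile_length_px total length of each perpendicular profile
#'   (default 40 px; even, at least 8).
#' @param samples_per_px sampling density along the profile (default 1).
#' @return A list of class `profile_params`.
#' @export
profile_params <- function(spacing_px = 3, profile_length_px = 40,
                           samples_per_px = 1) {
  stopifnot(spacing_px > 0, profile_length_px >= 8,
            profile_length_px %% 2 == 0, samples_per_px >= 1)
  structure(list(spacing_px = spacing_px,
                 profile_length_px = as.integer(profile_length_px),
                 samples_per_px = as.integer(samples_per_px)),
            class = "profile_params")
}

# bilinear interpolation at 0-based pixel-center coordinates
bilinear <- function(img, x, y) {
  W <- ncol(img); H <- nrow(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  y0 <- pmin(pmax(y0, 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  at <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x1)) +
    fy * ((1 - fx) * at(y1, x0) + fx * at(y1, x1))
}

#' Extract an intensity profile perpendicular to the membrane
#'
#' Samples the image by bilinear interpolation at equidistant signed offsets
#' in `[-L/2, +L/2]` along the given normal direction, centered on the anchor.
#' Profiles whose endpoints leave the image are marked rejected rather than
#' raising an error.
#'
#' @param image numeric matrix (one image page).
#' @param anchor `(x, y)` pixel coordinates of the profile center.
#' @param normal unit vector perpendicular to the local membrane tangent.
#' @param params a [profile_params()].
#' @return A list of class `line_profile` with `positions` (signed offsets,
#'   px), `intensities`, `anchor`, `normal` and `rejected`.
#' @export
extract_profile <- function(image, anchor, normal, params = profile_params()) {
  L <- params$profile_length_px
  positions <- seq(-L / 2, L / 2, by = 1 / params$samples_per_px)
  x <- anchor[1L] + positions * normal[1L]
  y <- anchor[2L] + positions * normal[2L]
  rejected <- any(x < 0 | x > ncol(image) - 1 | y < 0 | y > nrow(image) - 1)
  intensities <- if (rejected) rep(NA_real_, length(positions))
                 else bilinear(image, x, y)
  structure(list(positions = positions, intensities = intensities,
                 anchor = anchor, normal = normal, rejected = rejected),
            class = "line_profile")
}

#' Fit a Gaussian to a membrane cross-profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to a [line_profile()], initialized from the data (offset = min, amplitude =
#' max - min, center = position of the maximum, sigma = second moment of the
#' background-subtracted profile about the maximum). The membrane width
#' follows as `fwhm = 2 * sqrt(2 * log(2)) * sigma`.
#'
#' A fit is marked non-converged — and excluded from [summarize_fwhm()] — when
#' the optimizer fails, when `sigma` leaves `(0.5, L/4)` px, when the fitted
#' center lies more than `L/4` px off the anchor (e.g. a second membrane
#' dominating the window), or when the fitted amplitude is below twice the
#' profile's noise SD (no usable contrast). These rejection rules are this
#' package's own, configurable additions.
#'
#' @param profile a [line_profile()].
#' @param sigma_bounds_px allowed `(min, max)` for sigma; default
#'   `c(0.5, L/4)`.
#' @param center_window_px maximal |center| offset, default `L/4`.
#' @param min_contrast minimal amplitude in units of the noise SD (default 2).
#' @return An object of class `gaussian_fit` with elements `offset`,
#'   `amplitude`, `center_px`, `sigma_px`, `fwhm_px`, `rss` and `converged`.
#' @export
fit_gaussian_profile <- function(profile,
                                 sigma_bounds_px = NULL,
                                 center_window_px = NULL,
                                 min_contrast = 2) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$positions; y <- profile$intensities
  L <- max(x) - min(x)
  if (is.null(sigma_bounds_px)) sigma_bounds_px <- c(0.5, L / 4)
  if (is.null(center_window_px)) center_window_px <- L / 4
  failed <- function() structure(
    list(offset = NA_real_, amplitude = NA_real_, center_px = NA_real_,
         sigma_px = NA_real_, fwhm_px = NA_real_, rss = NA_real_,
         converged = FALSE), class = "gaussian_fit")
  if (profile$rejected || sum(is.finite(y)) < 8L) return(failed())
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (diff(range(y)) == 0) return(failed()) # flat profile
  off0 <- min(y); amp0 <- max(y) - off0
  c0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  s0 <- sqrt(sum(w * (x - c0)^2) / sum(w))
  s0 <- min(max(s0, sigma_bounds_px[1L] * 1.01), sigma_bounds_px[2L] * 0.99)
  resid_fn <- function(p) {
    p["off"] + p["amp"] * exp(-(x - p["ctr"])^2 / (2 * p["sig"]^2)) - y
  }
  jac_fn <- function(p) {
    e <- exp(-(x - p["ctr"])^2 / (2 * p["sig"]^2))
    cbind(off = 1, amp = e,
          ctr = p["amp"] * e * (x - p["ctr"]) / p["sig"]^2,
          sig = p["amp"] * e * (x - p["ctr"])^2 / p["sig"]^3)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(off = off0, amp = amp0, ctr = c0, sig = s0),
      fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(failed())
  p <- fit$par
  res <- -fit$fvec
  # residual SD doubles as the noise estimate: a clean single-peak profile
  # leaves near-zero residuals, while a misfit (second membrane in the
  # window) inflates them and trips the contrast rule
  noise_sd <- sqrt(sum(res^2) / max(1, length(y) - 4))
  ok <- is.finite(p[["sig"]]) && abs(p[["sig"]]) > sigma_bounds_px[1L] &&
    abs(p[["sig"]]) < sigma_bounds_px[2L] &&
    abs(p[["ctr"]]) <= center_window_px &&
    p[["amp"]] > 0 && p[["amp"]] >= min_contrast * noise_sd
  structure(list(
    offset = p[["off"]], amplitude = p[["amp"]], center_px = p[["ctr"]],
    sigma_px = abs(p[["sig"]]),
    fwhm_px = if (ok) 2 * sqrt(2 * log(2)) * abs(p[["sig"]]) else NA_real_,
    rss = sum(res^2), converged = ok), class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "gaussian_fit: offset %.3g, amplitude %.3g, center %.3g px, sigma %.3g px (FWHM %.3g px)\n",
      x$offset, x$amplitude, x$center_px, x$sigma_px, x$fwhm_px))
  else cat("gaussian_fit: not converged\n")
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(offset = object$offset, amplitude = object$amplitude,
    center_px = object$center_px, sigma_px = object$sigma_px)
}

#' Profile the FWHM of a membrane image along a contour
#'
#' Convenience wrapper running the full per-image pipeline:
#' [resample_contour()], [extract_profile()] at every anchor and
#' [fit_gaussian_profile()] on every profile.
#'
#' @param image numeric matrix (one image page).
#' @param contour a [roi_polyline()] tracing the membrane.
#' @param params a [profile_params()].
#' @return List of `gaussian_fit` objects (one per anchor).
#' @export
profile_image_fwhm <- function(image, contour, params = profile_params()) {
  rs <- resample_contour(contour, params$spacing_px)
  lapply(seq_len(nrow(rs$anchors)), function(i) {
    pr <- extract_profile(image, rs$anchors[i, ], rs$normals[i, ], params)
    fit_gaussian_profile(pr)
  })
}

#' Summarize FWHM fits into a resolution estimate
#'
#' Averages converged fits only. When `image` ids are supplied, per-image
#' means are computed as well and `mean_of_image_means` averages those — the
#' "average over at least 10 images" convention; the pooled mean over all
#' profiles is always reported.
#'
#' @param fits list of `gaussian_fit` objects.
#' @param pixel_size_nm pixel size used to convert px to nm.
#' @param image optional vector of image identifiers, one per fit.
#' @return Object of class `fwhm_summary`: `n_profiles_used`, `n_rejected`,
#'   `mean_fwhm_nm`, `sd_fwhm_nm`, and (when `image` given) `per_image` plus
#'   `mean_of_image_means_nm`.
#' @export
summarize_fwhm <- function(fits, pixel_size_nm, image = NULL) {
  fw_px <- vapply(fits, function(f) if (f$converged) f$fwhm_px else NA_real_,
                  numeric(1))
  used <- is.finite(fw_px)
  if (!any(used)) stop("no valid profiles: zero converged fits")
  fw_nm <- fw_px[used] * pixel_size_nm
  out <- list(n_profiles_used = sum(used), n_rejected = sum(!used),
              mean_fwhm_nm = mean(fw_nm),
              sd_fwhm_nm = if (sum(used) > 1L) stats::sd(fw_nm) else 0,
              pixel_size_nm = pixel_size_nm)
  if (!is.null(image)) {
    stopifnot(length(image) == length(fits))
    per <- tapply(fw_px[used] * pixel_size_nm, image[used], mean)
    out$per_image <- data.frame(image = names(per), mean_fwhm_nm = as.numeric(per),
                                row.names = NULL)
    out$mean_of_image_means_nm <- mean(as.numeric(per))
  }
  structure(out, class = "fwhm_summary")
}

#' @export
print.fwhm_summary <- function(x, ...) {
  cat(sprintf("fwhm_summary: %.1f +/- %.1f nm (n = %d used, %d rejected)\n",
              x$mean_fwhm_nm, x$sd_fwhm_nm, x$n_profiles_used, x$n_rejected))
  if (!is.null(x$mean_of_image_means_nm))
    cat(sprintf("  mean of %d image means: %.1f nm\n",
                nrow(x$per_image), x$mean_of_image_means_nm))
  invisible(x)
}

#' Confocal-to-STED resolution ratio
#'
#' Divides the mean membrane FWHM measured on confocal images by that of the
#' STED images of the same structures; values above 1 quantify the resolution
#' gain. The SD is propagated to first order:
#' `sd = ratio * sqrt((sd_c/m_c)^2 + (sd_s/m_s)^2)`.
#'
#' @param confocal,sted [summarize_fwhm()] results.
#' @return List with `ratio` and `sd`.
#' @export
resolution_ratio <- function(confocal, sted) {
  stopifnot(inherits(confocal, "fwhm_summary"), inherits(sted, "fwhm_summary"))
  if (sted$mean_fwhm_nm == 0) stop("STED mean FWHM is zero")
  r <- confocal$mean_fwhm_nm / sted$mean_fwhm_nm
  list(ratio = r,
       sd = r * sqrt((confocal$sd_fwhm_nm / confocal$mean_fwhm_nm)^2 +
                       (sted$sd_fwhm_nm / sted$mean_fwhm_nm)^2))
}
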