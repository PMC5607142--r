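#' Generalized polarization map
#'
#' Computes the pixel-wise generalized polarization
#' `GP = (I1 - I2) / (I1 + I2)` from an ordered (blue, typically 520–570 nm)
#' and a disordered (red, typically 620–700 nm) detection channel. GP is +1
#' for photons detected exclusively in the ordered channel (maximally ordered
#' lipid environment) and −1 for the disordered channel.
#'
#' Background pixels — where the GP ratio is dominated by noise — are masked:
#' a pixel is valid only when its summed intensity `I1 + I2` reaches at least
#' `mask_fraction` of the maximal summed intensity in the image. Masked pixels
#' carry `NaN`. GP values are never rescaled.
#'
#' An optional per-channel gain pair `gains = c(g1, g2)` multiplies the
#' channels before the ratio (G-factor style calibration); the default is no
#' correction.
#'
#' @param pair either a two-page [image_stack()] (page 1 = ordered channel
#'   `I1`, page 2 = disordered channel `I2`) or a numeric matrix `I1`.
#' @param i2 the disordered-channel matrix when `pair` is a matrix.
#' @param mask_fraction background threshold as a fraction of the maximal
#'   summed intensity, in `[0, 1)`; default 0.1.
#' @param gains optional `c(g1, g2)` channel gains.
#' @return Object of class `gp_map`: `gp` (matrix in `[-1, 1]` with `NaN` at
#'   masked pixels), `mask` (logical), `threshold_used`, `pixel_size_nm`.
#' @export
compute_gp_map <- function(pair, i2 = NULL, mask_fraction = 0.1,
                           gains = c(1, 1)) {
  if (inherits(pair, "image_stack")) {
    if (length(pair$pages) != 2L)
      stop("GP needs exactly two channel pages (ordered, disordered)")
    i1 <- pair$pages[[1L]]; i2 <- pair$pages[[2L]]
    px <- pair$pixel_size_nm
  } else {
    i1 <- pair
    if (is.null(i2)) stop("supply the disordered channel 'i2'")
    px <- NA_real_
  }
  stopifnot(all(dim(i1) == dim(i2)))
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("'mask_fraction' must lie in [0, 1)")
  i1 <- i1 * gains[1L]; i2 <- i2 * gains[2L]
  total <- i1 + i2
  mx <- max(total, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    warning("all-zero channel pair: fully masked GP map")
    mask <- matrix(FALSE, nrow(i1), ncol(i1))
    thr <- 0
  } else {
    thr <- mask_fraction * mx
    mask <- is.finite(total) & total >= thr & total > 0
  }
  gp <- (i1 - i2) / total
  gp[!mask] <- NaN
  structure(list(gp = gp, mask = mask, threshold_used = thr,
                 pixel_size_nm = px), class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("gp_map: %d x %d px, %d valid pixels (threshold %.3g)\n",
              nrow(x$gp), ncol(x$gp), sum(x$mask), x$threshold_used))
  if (any(x$mask))
    cat(sprintf("  GP range: %.3f .. %.3f\n",
                min(x$gp[x$mask]), max(x$gp[x$mask])))
  invisible(x)
}

#' ROI statistics on a GP map
#'
#' Mean and SD of the valid GP pixels inside each ROI (arithmetic mean of
#' per-pixel GP values; `method = "intensity_weighted"` would require the raw
#' channels and is offered by [roi_gp_stats_weighted()]). Pixels inside the
#' ROI but masked are excluded and counted separately.
#'
#' @param map a [compute_gp_map()] result.
#' @param rois a [roi_set()] (or a single ROI object).
#' @return `data.frame` with one row per ROI: `label`, `mean_gp`, `sd_gp`,
#'   `n_pixels` (valid), `n_masked`.
#' @export
roi_gp_stats <- function(map, rois) {
  stopifnot(inherits(map, "gp_map"))
  if (inherits(rois, "roi")) rois <- roi_set(list(roi = rois))
  stopifnot(inherits(rois, "roi_set"))
  rows <- lapply(names(rois$rois), function(lab) {
    r <- rois$rois[[lab]]
    if (inherits(r, "roi_polyline") && !r$closed) return(NULL) # open contour
    sel <- roi_pixel_mask(r, dim(map$gp))
    vals <- map$gp[sel & map$mask]
    if (length(vals) == 0L)
      stop(sprintf("ROI '%s' contains no valid (unmasked) pixels", lab))
    data.frame(label = lab, mean_gp = mean(vals),
               sd_gp = if (length(vals) > 1L) stats::sd(vals) else 0,
               n_pixels = length(vals), n_masked = sum(sel & !map$mask))
  })
  do.call(rbind, rows)
}

#' GP of summed ROI intensities
#'
#' The alternative ROI statistic: GP of the summed channel intensities inside
#' the ROI, `GP = (sum I1 - sum I2)/(sum I1 + sum I2)`, which weights pixels
#' by brightness.
#'
#' @param pair two-page [image_stack()] (ordered, disordered).
#' @param rois a [roi_set()].
#' @param map optional [compute_gp_map()] result whose mask restricts the sums.
#' @return `data.frame` with `label` and `gp_of_sums`.
#' @export
roi_gp_stats_weighted <- function(pair, rois, map = NULL) {
  stopifnot(inherits(pair, "image_stack"), length(pair$pages) == 2L)
  if (inherits(rois, "roi")) rois <- roi_set(list(roi = rois))
  i1 <- pair$pages[[1L]]; i2 <- pair$pages[[2L]]
  valid <- if (is.null(map)) matrix(TRUE, nrow(i1), ncol(i1)) else map$mask
  rows <- lapply(names(rois$rois), function(lab) {
    r <- rois$rois[[lab]]
    if (inherits(r, "roi_polyline") && !r$closed) return(NULL)
    sel <- roi_pixel_mask(r, dim(i1)) & valid
    s1 <- sum(i1[sel]); s2 <- sum(i2[sel])
    if (s1 + s2 <= 0) stop(sprintf("ROI '%s' has no signal", lab))
    data.frame(label = lab, gp_of_sums = (s1 - s2) / (s1 + s2))
  })
  do.call(rbind, rows)
}

#' Difference in GP between two membrane environments
#'
#' The interdomain GP difference (ordered minus disordered), with the SD
#' propagated to first order (`sqrt(sd1^2 + sd2^2)`). Because absolute GP
#' depends strongly on probe, microscope and detection bands, this relative
#' quantity is the more transferable readout.
#'
#' @param stats_ordered,stats_disordered single rows of [roi_gp_stats()]
#'   output.
#' @return List with `difference` and `sd`.
#' @export
interdomain_difference <- function(stats_ordered, stats_disordered) {
  list(difference = stats_ordered$mean_gp - stats_disordered$mean_gp,
       sd = sqrt(stats_ordered$sd_gp^2 + stats_disordered$sd_gp^2))
}

#' Render a GP map with the red-to-blue lookup table
#'
#' Maps GP linearly onto a red(+1)-to-blue(−1) color scale: the RGB triple is
#' interpolated linearly between pure blue at GP −1, through the midpoint
#' (0.5, 0, 0.5) at GP 0, to pure red at +1. Masked pixels render black.
#' When an `intensity` image is supplied, pixel brightness is modulated by
#' `intensity / max(intensity)`.
#'
#' @param map a [compute_gp_map()] result.
#' @param intensity optional non-negative matrix (e.g. `I1 + I2`).
#' @return `H x W x 3` RGB array in `[0, 1]`, suitable for `png::writePNG`.
#' @export
render_gp_colormap <- function(map, intensity = NULL) {
  stopifnot(inherits(map, "gp_map"))
  gp <- map$gp
  t01 <- (pmin(pmax(gp, -1), 1) + 1) / 2 # 0 = blue, 1 = red
  r <- t01; b <- 1 - t01; g <- matrix(0, nrow(gp), ncol(gp))
  r[!map$mask] <- 0; b[!map$mask] <- 0
  if (!is.null(intensity)) {
    stopifnot(all(dim(intensity) == dim(gp)))
    sc <- intensity / max(intensity, na.rm = TRUE)
    sc[!is.finite(sc)] <- 0
    r <- r * sc; g <- g * sc; b <- b * sc
  }
  out <- array(0, dim = c(nrow(gp), ncol(gp), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}
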