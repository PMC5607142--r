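#' Photobleaching curve from a time-series stack
#'
#' Computes the mean intensity over a fixed membrane ROI in every frame of a
#' sequential acquisition and normalizes the series to the first frame
#' (frame 0 is exactly 1 by construction). The same ROI is applied to all
#' frames; no drift correction or per-frame re-segmentation is attempted.
#' Optionally the mean of a background ROI is subtracted per frame first.
#'
#' @param stack an [image_stack()] with `axis_kind = "time"` and >= 2 frames.
#' @param roi membrane ROI (circle or closed polyline).
#' @param background_roi optional background ROI whose per-frame mean is
#'   subtracted before normalization.
#' @return Object of class `bleach_curve`: `frame` (0-based),
#'   `normalized_intensity`, `raw_mean`, `roi_label`.
#' @export
bleach_curve <- function(stack, roi, background_roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_kind != "time") stop("bleach analysis needs a time-axis stack")
  if (length(stack$pages) < 2L) stop("need at least 2 frames")
  sel <- roi_pixel_mask(roi, dim(stack$pages[[1L]]))
  if (!any(sel)) stop("ROI selects no pixels")
  m <- vapply(stack$pages, function(p) mean(p[sel]), numeric(1))
  if (!is.null(background_roi)) {
    bsel <- roi_pixel_mask(background_roi, dim(stack$pages[[1L]]))
    m <- m - vapply(stack$pages, function(p) mean(p[bsel]), numeric(1))
  }
  if (m[1L] == 0) stop("frame-0 mean is zero; cannot normalize")
  norm <- m / m[1L]
  if (any(norm > 1 + 1e-12) && norm[length(norm)] > 1)
    warning("intensity increases over the series (brightening artifact)")
  structure(list(frame = seq_along(m) - 1L, normalized_intensity = norm,
                 raw_mean = m, roi_label = roi$purpose %||% "roi"),
            class = "bleach_curve")
}

#' @export
print.bleach_curve <- function(x, ...) {
  n <- length(x$frame)
  cat(sprintf("bleach_curve: %d frames, final relative intensity %.3f\n",
              n, x$normalized_intensity[n]))
  invisible(x)
}

#' Fractional signal loss after a number of frames
#'
#' `1 - normalized_intensity[n_frames - 1]` (0-based frame index), i.e. the
#' fraction of the initial signal lost by the `n_frames`-th acquired image.
#' A brightening series yields a negative loss, returned as-is with a warning.
#'
#' @param curve a [bleach_curve()].
#' @param n_frames number of acquired frames to evaluate at (defaults to the
#'   whole series).
#' @return Fractional loss in `[-Inf, 1]` (0 = no loss).
#' @export
fractional_loss <- function(curve, n_frames = length(curve$frame)) {
  stopifnot(inherits(curve, "bleach_curve"))
  if (n_frames < 1L || n_frames > length(curve$frame))
    stop("'n_frames' outside the recorded series")
  loss <- 1 - curve$normalized_intensity[n_frames]
  if (loss < 0) warning("negative loss: signal brightened over the series")
  loss
}

#' Fit a single-exponential decay to a bleaching curve
#'
#' Least-squares fit of `survival^k` (k = 0-based frame index) to the
#' normalized curve, with `survival` constrained to `(0, 1.1]` — values
#' slightly above 1 accommodate noise around a non-bleaching series.
#'
#' @param curve a [bleach_curve()] with >= 3 frames.
#' @return Object of class `decay_fit`: `survival_per_frame`, `rss`.
#' @export
fit_decay <- function(curve) {
  stopifnot(inherits(curve, "bleach_curve"))
  k <- curve$frame; y <- curve$normalized_intensity
  if (length(k) < 3L) stop("need at least 3 frames to fit a decay")
  if (any(!is.finite(y))) stop("non-finite intensities in curve")
  rss <- function(s) sum((y - s^k)^2)
  opt <- stats::optimize(rss, c(1e-6, 1.1), tol = 1e-10)
  structure(list(survival_per_frame = opt$minimum, rss = opt$objective),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: survival %.5f per frame (rss %.3g)\n",
              x$survival_per_frame, x$rss))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(survival_per_frame = object$survival_per_frame)
}
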