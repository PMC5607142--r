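#' Extract an ROI emission spectrum from a lambda stack
#'
#' Computes the mean intensity over the ROI pixels in every spectral window of
#' the stack; the spectral axis is the window centers (midpoints of the band
#' edges). With `normalize = TRUE` the trace is divided by its maximum — the
#' standard presentation of emission spectra of polarity-sensitive dyes.
#'
#' @param stack an [image_stack()] with `axis_kind = "wavelength"`.
#' @param roi an ROI (circle or closed polyline).
#' @param normalize divide by the maximal window mean?
#' @return Object of class `spectrum_trace`: `wavelengths_nm`, `intensities`,
#'   `normalized`.
#' @export
extract_spectrum <- function(stack, roi, normalize = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_kind != "wavelength")
    stop("spectrum extraction needs a wavelength-axis stack")
  sel <- roi_pixel_mask(roi, dim(stack$pages[[1L]]))
  if (!any(sel)) stop("ROI selects no pixels")
  ints <- vapply(stack$pages, function(p) mean(p[sel]), numeric(1))
  if (normalize) {
    mx <- max(ints)
    if (mx <= 0) stop("all-zero spectrum cannot be normalized")
    ints <- ints / mx
  }
  structure(list(wavelengths_nm = band_centers(stack), intensities = ints,
                 normalized = normalize), class = "spectrum_trace")
}

#' @export
print.spectrum_trace <- function(x, ...) {
  cat(sprintf("spectrum_trace: %d windows, %g-%g nm%s\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a spectrum trace to unit maximum
#'
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param trace a `spectrum_trace`.
#' @return The normalized trace.
#' @export
normalize_spectrum <- function(trace) {
  stopifnot(inherits(trace, "spectrum_trace"))
  mx <- max(trace$intensities)
  if (mx <= 0) stop("all-zero spectrum cannot be normalized")
  trace$intensities <- trace$intensities / mx
  trace$normalized <- TRUE
  trace
}

#' Emission peak position of a spectrum trace
#'
#' `method = "argmax_bin"` returns the center of the maximal window —
#' reading the peak straight off the binned spectrum. `"parabolic"` (default)
#' refines it by the vertex of the parabola through the maximal window and its
#' two neighbors, recovering sub-window peak positions; at the axis edge it
#' falls back to the bin center.
#'
#' @param trace a `spectrum_trace` with at least 3 windows.
#' @param method `"parabolic"` or `"argmax_bin"`.
#' @return List with `peak_nm` and `method`.
#' @export
peak_wavelength <- function(trace, method = c("parabolic", "argmax_bin")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "spectrum_trace"))
  wl <- trace$wavelengths_nm; y <- trace$intensities
  if (length(wl) < 3L) stop("need at least 3 spectral windows")
  if (all(y == 0)) stop("all-zero spectrum has no peak")
  i <- which.max(y)
  peak <- wl[i]
  if (method == "parabolic" && i > 1L && i < length(y)) {
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom < 0) {
      step <- (wl[i + 1L] - wl[i - 1L]) / 2
      peak <- wl[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * step
    }
  }
  list(peak_nm = peak, method = method)
}

#' Spectral shift between ordered and disordered phases
#'
#' Peak position of the disordered-phase spectrum minus that of the ordered
#' phase; positive values are red shifts. Polarity-sensitive probes useful for
#' two-channel ratiometric imaging show shifts of several tens of nm.
#'
#' @param ordered,disordered `spectrum_trace`s on the same wavelength axis.
#' @param method forwarded to [peak_wavelength()].
#' @return Shift in nm.
#' @export
peak_shift <- function(ordered, disordered,
                       method = c("parabolic", "argmax_bin")) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(ordered$wavelengths_nm, disordered$wavelengths_nm)))
    stop("traces are on different wavelength axes")
  peak_wavelength(disordered, method)$peak_nm -
    peak_wavelength(ordered, method)$peak_nm
}

#' Per-window ordered/disordered intensity ratio
#'
#' For every spectral window, the ratio of the mean intensity in the ordered
#' ROI to that in the disordered ROI. Windows with zero disordered mean are
#' flagged `excluded` (ratio `NA`). For probes with a red-shifting spectrum
#' the ratio is > 1 in blue windows and < 1 in red windows, crossing unity
#' once — the basis for choosing the two GP detection bands.
#'
#' @param stack wavelength-axis [image_stack()].
#' @param roi_ordered,roi_disordered ROIs for the two phases.
#' @return `data.frame` with `wavelength_nm`, `ratio`, `excluded`.
#' @export
channel_intensity_ratio <- function(stack, roi_ordered, roi_disordered) {
  o <- extract_spectrum(stack, roi_ordered, normalize = FALSE)
  d <- extract_spectrum(stack, roi_disordered, normalize = FALSE)
  excl <- d$intensities == 0
  data.frame(wavelength_nm = o$wavelengths_nm,
             ratio = ifelse(excl, NA_real_, o$intensities / d$intensities),
             excluded = excl)
}

#' Recombine lambda-stack windows into a two-channel image
#'
#' Sums all windows whose centers fall inside `band_a` into channel 1 and
#' those inside `band_b` into channel 2 (windows straddling a band edge are
#' assigned by center position), reproducing a two-channel acquisition from a
#' spectral one — e.g. a green 500–530 nm GFP channel and a red 570–691 nm
#' membrane-dye channel.
#'
#' @param stack wavelength-axis [image_stack()].
#' @param band_a,band_b `c(low, high)` nm ranges.
#' @return A two-page `"channel"` [image_stack()] with the requested bands as
#'   metadata.
#' @export
recombine_bands <- function(stack, band_a, band_b) {
  stopifnot(inherits(stack, "image_stack"))
  ctr <- band_centers(stack)
  pick <- function(band) {
    sel <- ctr >= band[1L] & ctr <= band[2L]
    if (!any(sel)) stop(sprintf("no windows inside band %g-%g nm",
                                band[1L], band[2L]))
    Reduce(`+`, stack$pages[sel])
  }
  image_stack(list(pick(band_a), pick(band_b)), axis_kind = "channel",
              pixel_size_nm = stack$pixel_size_nm,
              band_edges_nm = if (band_a[2L] <= band_b[1L])
                list(as.numeric(band_a), as.numeric(band_b)) else NULL)
}
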