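#' Command-line pipeline runners
#'
#' Thin, file-oriented wrappers over the analysis functions, backing the
#' `memgp` command-line interface (`inst/scripts/memgp`). Each runner writes
#' its results as CSV (one header row, "." decimal separator) plus a
#' machine-readable JSON record of the run parameters, so that re-running with
#' the same inputs and seed reproduces the outputs bit-identically.
#'
#' @param out_dir output directory (created if missing).
#' @param preset phantom preset name, see [phantom_preset()].
#' @param psf `"sted"`, `"confocal"`, or a FWHM in nm.
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed.
#' @return The output directory, invisibly.
#' @name pipelines
NULL

write_params <- function(out_dir, module, params) {
  jsonlite::write_json(
    list(module = module, package = "memgp",
         version = as.character(utils::packageVersion("memgp")),
         parameters = params),
    file.path(out_dir, paste0(module, "_params.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname pipelines
#' @export
run_simulate <- function(preset, psf = "sted", noise = "poisson", seed = 1,
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- if (psf %in% names(psf_presets())) psf_presets()[[psf]] else as.numeric(psf)
  spec <- phantom_preset(preset, psf_fwhm_nm = fw, noise = noise, seed = seed)
  ph <- if (spec$n_frames > 1L) render_bleach_series(spec) else render_phantom(spec)
  write_image_stack(ph$stack, file.path(out_dir, "phantom.tif"))
  save_rois(ph$rois, file.path(out_dir, "phantom_rois.json"))
  jsonlite::write_json(
    list(gp_true = as.list(ph$truth$gp_true),
         psf_fwhm_nm = ph$truth$psf_fwhm_nm,
         bleach_survival_per_frame = ph$truth$bleach_survival_per_frame,
         seed = seed),
    file.path(out_dir, "phantom_truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(ph$stack$band_edges_nm))
    utils::write.csv(data.frame(
      low_nm = vapply(ph$stack$band_edges_nm, `[`, numeric(1), 1L),
      high_nm = vapply(ph$stack$band_edges_nm, `[`, numeric(1), 2L)),
      file.path(out_dir, "phantom_bands.csv"), row.names = FALSE)
  write_params(out_dir, "simulate",
               list(preset = preset, psf = psf, noise = noise, seed = seed))
  invisible(out_dir)
}

#' @param image path to a TIFF image (page 1 is profiled).
#' @param roi path to an ROI JSON with a membrane polyline.
#' @param pixel_size_nm,spacing,length profile sampling settings.
#' @rdname pipelines
#' @export
run_fwhm <- function(image, roi, pixel_size_nm = 20, spacing = 3, length = 40,
                     out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- read_image_stack(image, pixel_size_nm = pixel_size_nm)
  rois <- load_rois(roi)
  contour <- Find(function(r) inherits(r, "roi_polyline"), rois$rois)
  if (is.null(contour)) stop("ROI file contains no membrane polyline")
  params <- profile_params(spacing_px = spacing, profile_length_px = length)
  rs <- resample_contour(contour, params$spacing_px)
  fits <- profile_image_fwhm(stack$pages[[1L]], contour, params)
  per <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(anchor_x = rs$anchors[i, 1L], anchor_y = rs$anchors[i, 2L],
               offset = f$offset, amplitude = f$amplitude,
               center_px = f$center_px, sigma_px = f$sigma_px,
               fwhm_nm = f$fwhm_px * pixel_size_nm, converged = f$converged)
  }))
  utils::write.csv(per, file.path(out_dir, "fwhm_profiles.csv"),
                   row.names = FALSE)
  sm <- summarize_fwhm(fits, pixel_size_nm)
  utils::write.csv(data.frame(
    mean_fwhm_nm = sm$mean_fwhm_nm, sd_fwhm_nm = sm$sd_fwhm_nm,
    n_profiles_used = sm$n_profiles_used, n_rejected = sm$n_rejected),
    file.path(out_dir, "fwhm_summary.csv"), row.names = FALSE)
  write_params(out_dir, "fwhm",
               list(image = image, roi = roi, pixel_size_nm = pixel_size_nm,
                    spacing = spacing, length = length))
  invisible(out_dir)
}

#' @param mask_fraction background mask threshold, see [compute_gp_map()].
#' @rdname pipelines
#' @export
run_gpmap <- function(image, roi = NULL, mask_fraction = 0.1,
                      pixel_size_nm = 20, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- read_image_stack(image, axis_kind = "channel",
                            pixel_size_nm = pixel_size_nm)
  map <- compute_gp_map(stack, mask_fraction = mask_fraction)
  write_image_stack(image_stack(list(map$gp), pixel_size_nm = pixel_size_nm),
                    file.path(out_dir, "gp_map.tif"))
  if (requireNamespace("png", quietly = TRUE)) {
    total <- stack$pages[[1L]] + stack$pages[[2L]]
    png::writePNG(render_gp_colormap(map, total),
                  file.path(out_dir, "gp_map.png"))
  }
  if (!is.null(roi)) {
    stats <- roi_gp_stats(map, load_rois(roi))
    utils::write.csv(stats, file.path(out_dir, "gp_roi_stats.csv"),
                     row.names = FALSE)
  }
  write_params(out_dir, "gpmap",
               list(image = image, roi = roi, mask_fraction = mask_fraction,
                    pixel_size_nm = pixel_size_nm))
  invisible(out_dir)
}

#' @param stack path to a lambda-stack TIFF.
#' @param bands band sidecar: either a CSV with `low_nm,high_nm` columns or a
#'   string `"start:stop"` expanded into consecutive 9-nm windows.
#' @param recombine optional `"a_low:a_high,b_low:b_high"` band pair for
#'   [recombine_bands()].
#' @rdname pipelines
#' @export
run_spectra <- function(stack, roi, bands, recombine = NULL,
                        pixel_size_nm = 20, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- if (file.exists(bands)) {
    tb <- utils::read.csv(bands)
    lapply(seq_len(nrow(tb)), function(i) c(tb$low_nm[i], tb$high_nm[i]))
  } else {
    rg <- as.numeric(strsplit(bands, ":", fixed = TRUE)[[1L]])
    lows <- seq(rg[1L], rg[2L] - 1e-9, by = 9)
    lapply(lows, function(l) c(l, l + 9))
  }
  st <- read_image_stack(stack, axis_kind = "wavelength",
                         pixel_size_nm = pixel_size_nm, band_edges_nm = edges)
  rois <- load_rois(roi)
  specs <- lapply(rois$rois, function(r) extract_spectrum(st, r))
  out <- data.frame(wavelength_nm = band_centers(st))
  for (lab in names(specs)) out[[lab]] <- specs[[lab]]$intensities
  utils::write.csv(out, file.path(out_dir, "spectra.csv"), row.names = FALSE)
  if (all(c("ordered", "disordered") %in% names(rois$rois))) {
    ratio <- channel_intensity_ratio(st, rois$rois$ordered,
                                     rois$rois$disordered)
    utils::write.csv(ratio, file.path(out_dir, "intensity_ratio.csv"),
                     row.names = FALSE)
    shift <- peak_shift(specs$ordered, specs$disordered)
    utils::write.csv(data.frame(peak_shift_nm = shift),
                     file.path(out_dir, "peak_shift.csv"), row.names = FALSE)
  }
  if (!is.null(recombine)) {
    pr <- lapply(strsplit(recombine, ",", fixed = TRUE)[[1L]],
                 function(s) as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]]))
    rc <- recombine_bands(st, pr[[1L]], pr[[2L]])
    write_image_stack(rc, file.path(out_dir, "recombined.tif"))
  }
  write_params(out_dir, "spectra",
               list(stack = stack, roi = roi, bands = bands,
                    recombine = recombine))
  invisible(out_dir)
}

#' @param frames number of frames at which the loss is reported.
#' @rdname pipelines
#' @export
run_bleach <- function(stack, roi, frames = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- read_image_stack(stack, axis_kind = "time")
  rois <- load_rois(roi)
  r <- Find(function(x) inherits(x, "roi_circle"), rois$rois) %||%
    rois$rois[[1L]]
  curve <- bleach_curve(st, r)
  utils::write.csv(data.frame(frame = curve$frame,
                              normalized_intensity = curve$normalized_intensity,
                              raw_mean = curve$raw_mean),
                   file.path(out_dir, "bleach_curve.csv"), row.names = FALSE)
  n <- frames %||% length(curve$frame)
  fit <- fit_decay(curve)
  utils::write.csv(data.frame(
    survival_per_frame = fit$survival_per_frame, rss = fit$rss,
    fractional_loss = fractional_loss(curve, n), n_frames = n),
    file.path(out_dir, "bleach_fit.csv"), row.names = FALSE)
  write_params(out_dir, "bleach",
               list(stack = stack, roi = roi, frames = frames))
  invisible(out_dir)
}
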