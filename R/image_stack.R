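#' Multi-page image stack
#'
#' An `image_stack` is the package's container for grayscale image data: a
#' list of equally sized 2-D intensity matrices ("pages") together with the
#' semantics of the page axis and the pixel size. The page axis can be a
#' detection-channel axis (ordered/disordered band pair), a wavelength axis
#' (lambda stack of narrow spectral windows), a time axis (sequential frames),
#' or absent (`"single"`).
#'
#' Intensities are treated as linear, photon-proportional counts; no detector
#' calibration is applied anywhere in the package. `NaN` values are permitted
#' (they mark masked pixels in derived maps) and survive TIFF round-trips.
#'
#' @param pages list of numeric matrices, all with identical dimensions.
#' @param axis_kind meaning of the page axis: one of `"single"`, `"channel"`,
#'   `"wavelength"`, `"time"`.
#' @param pixel_size_nm pixel size in nanometres (default 20, the typical
#'   STED-optimized sampling).
#' @param band_edges_nm optional list of `c(low, high)` wavelength pairs (nm),
#'   one per page. Required when `axis_kind = "wavelength"`; edges must be
#'   ascending and non-overlapping.
#' @return An object of class `image_stack`.
#' @seealso [read_image_stack()], [write_image_stack()]
#' @export
image_stack <- function(pages,
                        axis_kind = c("single", "channel", "wavelength", "time"),
                        pixel_size_nm = 20,
                        band_edges_nm = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (is.matrix(pages)) pages <- list(pages)
  if (!is.list(pages) || length(pages) == 0L)
    stop("'pages' must be a non-empty list of matrices")
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!is.matrix(p) || !is.numeric(p))
      stop(sprintf("page %d is not a numeric matrix", i))
    if (!all(dim(p) == dim(pages[[1L]])))
      stop(sprintf("page %d has dimensions %dx%d, expected %dx%d",
                   i, nrow(p), ncol(p), nrow(pages[[1L]]), ncol(pages[[1L]])))
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a positive number")
  if (!is.null(band_edges_nm)) {
    band_edges_nm <- lapply(band_edges_nm, as.numeric)
    if (length(band_edges_nm) != length(pages))
      stop("'band_edges_nm' must have one (low, high) pair per page")
    for (b in band_edges_nm)
      if (length(b) != 2L || b[1L] >= b[2L])
        stop("each band must be a (low, high) pair with low < high")
    lows <- vapply(band_edges_nm, `[`, numeric(1), 1L)
    highs <- vapply(band_edges_nm, `[`, numeric(1), 2L)
    if (length(lows) > 1L && any(lows[-1L] < highs[-length(highs)]))
      stop("bands must be ascending and non-overlapping")
  } else if (axis_kind == "wavelength") {
    stop("axis_kind = \"wavelength\" requires 'band_edges_nm' (one pair per page)")
  }
  structure(
    list(pages = pages, axis_kind = axis_kind,
         pixel_size_nm = pixel_size_nm, band_edges_nm = band_edges_nm),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pages[[1L]])
  cat(sprintf("image_stack: %d page(s) of %d x %d px (axis: %s, pixel %g nm)\n",
              length(x$pages), d[1L], d[2L], x$axis_kind, x$pixel_size_nm))
  if (!is.null(x$band_edges_nm)) {
    b <- vapply(x$band_edges_nm, function(e) sprintf("%g-%g", e[1], e[2]), "")
    cat("  bands (nm):", paste(b, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$pages)

#' Band centers of a wavelength or channel stack
#'
#' @param stack an [image_stack()] with `band_edges_nm` metadata.
#' @return Numeric vector of band midpoints in nm.
#' @export
band_centers <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$band_edges_nm))
    stop("stack has no band metadata")
  vapply(stack$band_edges_nm, function(e) mean(e), numeric(1))
}

#' Read a grayscale TIFF into an image stack
#'
#' Reads single- or multi-page grayscale TIFF files (16-bit integer or 32-bit
#' IEEE float). Integer data are returned as the stored counts; float data are
#' returned bit-exactly, including `NaN`.
#'
#' @param path path to a TIFF file.
#' @param axis_kind,pixel_size_nm,band_edges_nm metadata attached to the
#'   result; see [image_stack()].
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path,
                             axis_kind = c("single", "channel", "wavelength", "time"),
                             pixel_size_nm = 20,
                             band_edges_nm = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3L)
      stop(sprintf("page %d of '%s' is not grayscale (RGB/multi-sample data)",
                   i, path))
    storage.mode(pages[[i]]) <- "double"
  }
  image_stack(pages, axis_kind = axis_kind, pixel_size_nm = pixel_size_nm,
              band_edges_nm = band_edges_nm)
}

#' Write an image stack as a lossless grayscale TIFF
#'
#' Writes a multi-page, uncompressed grayscale TIFF. The default 32-bit IEEE
#' float encoding is fully lossless for any values, including `NaN`; the
#' 16-bit unsigned integer encoding is lossless for integer counts in
#' `[0, 65535]`.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param format `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, format = c("float32", "uint16")) {
  stopifnot(inherits(stack, "image_stack"))
  format <- match.arg(format)
  if (length(stack$pages) == 0L) stop("cannot write a stack with no pages")
  if (format == "uint16") {
    vals <- unlist(stack$pages, use.names = FALSE)
    if (anyNA(vals) || any(vals < 0 | vals > 65535 | vals != round(vals)))
      stop("uint16 format requires integer values in [0, 65535] and no NaN")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write_tiff_pages(con, stack$pages, format)
  invisible(path)
}

# Minimal baseline-TIFF encoder (little-endian, one strip per page,
# uncompressed, SampleFormat IEEEFP or unsigned int). Written by hand because
# the linked libtiff wrapper only stores [0,1]-scaled integer data.
write_tiff_pages <- function(con, pages, format) {
  bps <- if (format == "float32") 32L else 16L
  bytes_pp <- bps / 8L
  sample_format <- if (format == "float32") 3L else 1L
  n <- length(pages)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  data_bytes <- h * w * bytes_pp
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  data_off <- 8L + (seq_len(n) - 1L) * (data_bytes + ifd_bytes)
  ifd_off <- data_off + data_bytes

  writeChar("II", con, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1L]), con, size = 4, endian = "little")

  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT: value left-justified in 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    v <- as.vector(t(pages[[i]])) # row-major
    if (format == "float32") {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else {
      # uint16 via raw to avoid signed-short overflow
      r <- as.raw(rbind(as.integer(v) %% 256L, as.integer(v) %/% 256L))
      writeBin(r, con)
    }
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256L, 4L, 1L, w)                 # ImageWidth
    tag(257L, 4L, 1L, h)                 # ImageLength
    tag(258L, 3L, 1L, bps)               # BitsPerSample
    tag(259L, 3L, 1L, 1L)                # Compression: none
    tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off[i])       # StripOffsets
    tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
    tag(278L, 4L, 1L, h)                 # RowsPerStrip
    tag(279L, 4L, 1L, data_bytes)        # StripByteCounts
    tag(339L, 3L, 1L, sample_format)     # SampleFormat
    writeBin(as.integer(if (i < n) ifd_off[i + 1L] else 0L), con,
             size = 4, endian = "little")
  }
  invisible(NULL)
}
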