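#' Region-of-interest geometry
#'
#' ROIs localize measurements on an image: a *polyline* traces a membrane
#' contour (ordered vertices, optionally closed), a *circle* selects a disc of
#' pixels (domain, vesicle or background spots). Coordinates are 0-based
#' pixel-center `(x, y)` pairs with `x` the column and `y` the row.
#'
#' @param vertices numeric matrix (or coercible) with two columns `(x, y)`;
#'   at least two rows, consecutive vertices distinct.
#' @param closed logical; is the polyline a closed contour?
#' @param purpose free-text tag (`"membrane"`, `"domain"`, `"surround"`,
#'   `"vesicle"`, `"background"`, ...).
#' @return An object of class `roi_polyline` or `roi_circle`.
#' @export
roi_polyline <- function(vertices, closed = FALSE, purpose = "membrane") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("'vertices' must be an n x 2 matrix with n >= 2")
  storage.mode(vertices) <- "double"
  d <- diff(vertices)
  if (any(rowSums(abs(d)) == 0))
    stop("consecutive vertices must be distinct")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, closed = isTRUE(closed),
                 purpose = purpose),
            class = c("roi_polyline", "roi"))
}

#' @param center numeric `(x, y)` pair, pixel coordinates.
#' @param radius circle radius in pixels (positive).
#' @rdname roi_polyline
#' @export
roi_circle <- function(center, radius, purpose = "domain") {
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("'center' must be a finite (x, y) pair")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive number")
  structure(list(center = center, radius = as.numeric(radius),
                 purpose = purpose),
            class = c("roi_circle", "roi"))
}

#' @param rois named list of `roi_polyline`/`roi_circle` objects; names are
#'   the ROI labels and must be unique.
#' @rdname roi_polyline
#' @export
roi_set <- function(rois) {
  if (!is.list(rois) || is.null(names(rois)) || any(names(rois) == ""))
    stop("'rois' must be a named list")
  if (anyDuplicated(names(rois)))
    stop(sprintf("duplicate ROI label: '%s'",
                 names(rois)[duplicated(names(rois))][1L]))
  for (r in rois)
    if (!inherits(r, "roi")) stop("all elements must be ROI objects")
  structure(list(rois = rois), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set with %d ROI(s):\n", length(x$rois)))
  for (nm in names(x$rois)) {
    r <- x$rois[[nm]]
    if (inherits(r, "roi_circle"))
      cat(sprintf("  %s: circle center (%g, %g) r=%g [%s]\n",
                  nm, r$center[1], r$center[2], r$radius, r$purpose))
    else
      cat(sprintf("  %s: polyline, %d vertices%s [%s]\n", nm,
                  nrow(r$vertices), if (r$closed) " (closed)" else "",
                  r$purpose))
  }
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$rois)

#' Read and write ROI sets as JSON sidecars
#'
#' ROIs are persisted as a documented JSON schema rather than a binary format:
#' `{"rois": {"<label>": {"type": "polyline"|"circle", "purpose": "<tag>",
#' "vertices": [[x,y],...] | "center": [x,y], "radius": r,
#' "closed": true|false}}}`. Round-trips preserve coordinates to full double
#' precision.
#'
#' @param path JSON file path.
#' @return `load_rois` returns a [roi_set()]; `save_rois` returns `path`
#'   invisibly.
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$rois)) stop("malformed ROI file: no 'rois' object")
  labs <- names(doc$rois)
  if (is.null(labs) || anyDuplicated(labs))
    stop("malformed ROI file: missing or duplicate labels")
  rois <- lapply(doc$rois, function(r) {
    purpose <- if (is.null(r$purpose)) "unspecified" else r$purpose
    if (identical(r$type, "polyline")) {
      v <- do.call(rbind, lapply(r$vertices, as.numeric))
      roi_polyline(v, closed = isTRUE(r$closed), purpose = purpose)
    } else if (identical(r$type, "circle")) {
      roi_circle(as.numeric(unlist(r$center)), as.numeric(r$radius),
                 purpose = purpose)
    } else stop(sprintf("unknown ROI type '%s'", r$type))
  })
  names(rois) <- labs
  roi_set(rois)
}

#' @param rois a [roi_set()].
#' @rdname load_rois
#' @export
save_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  enc <- lapply(rois$rois, function(r) {
    if (inherits(r, "roi_circle"))
      list(type = "circle", center = r$center, radius = r$radius,
           purpose = r$purpose)
    else
      list(type = "polyline",
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) r$vertices[i, ]),
           closed = r$closed, purpose = r$purpose)
  })
  jsonlite::write_json(list(rois = enc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize an ROI to a logical pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the ROI: within
#' `radius` of a circle's center, or inside the polygon spanned by a closed
#' polyline (even-odd rule). Open polylines cannot be rasterized.
#'
#' @param roi an ROI object.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the given dimensions.
#' @export
roi_pixel_mask <- function(roi, dim) {
  h <- dim[1L]; w <- dim[2L]
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)   # x = column index
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)  # y = row index
  if (inherits(roi, "roi_circle")) {
    (xs - roi$center[1L])^2 + (ys - roi$center[2L])^2 <= roi$radius^2
  } else if (inherits(roi, "roi_polyline")) {
    if (!roi$closed)
      stop("only closed polylines can be rasterized to a region")
    m <- point_in_polygon(as.vector(xs), as.vector(ys), roi$vertices)
    matrix(m, h, w)
  } else stop("not an ROI object")
}

# Even-odd ray casting, vectorized over query points.
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1L]; yi <- vertices[i, 2L]
    xj <- vertices[j, 1L]; yj <- vertices[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
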