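#' Calibrated single-channel micrograph
#'
#' A micrograph is an integer intensity matrix (rows are image rows, top row
#' first) carrying its bit depth and the physical pixel size. Pixel centers
#' sit at 0-based integer coordinates: column index `x`, row index `y`, with
#' the origin at the top-left pixel center.
#'
#' @param pixels Integer matrix of intensities.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param bit_depth 8 or 16.
#' @param channel_label Free-text channel description.
#' @return A `micrograph` object (matrix with calibration attributes).
#' @export
micrograph <- function(pixels, pixel_size_um, bit_depth = 16L,
                       channel_label = "") {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels)) abort("`pixels` must not contain NA.")
  if (min(pixels) < 0 || max(pixels) > maxval) {
    abort(sprintf("intensities must lie in [0, %d] for bit depth %d.",
                  maxval, bit_depth))
  }
  storage.mode(pixels) <- "integer"
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            bit_depth = as.integer(bit_depth),
            channel_label = as.character(channel_label),
            class = c("micrograph", "matrix", "array"))
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %d-bit, %.4g um/px%s\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              attr(x, "pixel_size_um"),
              if (nzchar(attr(x, "channel_label")))
                paste0(", ", attr(x, "channel_label")) else ""))
  cat(sprintf("  intensity range [%d, %d]\n", min(x), max(x)))
  invisible(x)
}

#' Pixel size of a micrograph
#' @param img A [micrograph()].
#' @return Pixel size in micrometres per pixel.
#' @export
pixel_size <- function(img) attr(img, "pixel_size_um")

#' Read a calibrated grayscale TIFF
#'
#' The calibration is never guessed: `pixel_size_um` must be supplied
#' explicitly (TIFF resolution tags from microscope exports are unreliable).
#'
#' @param path TIFF file path.
#' @param pixel_size_um Micrometres per pixel; required.
#' @param channel_label Optional channel description.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_um, channel_label = "") {
  if (missing(pixel_size_um)) {
    abort("`pixel_size_um` is required: supply the calibration explicitly.")
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(raw)) != 2L) {
    abort("multi-channel TIFF: convert to single-channel grayscale first.")
  }
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) {
    abort(sprintf("unsupported bit depth %s (need 8 or 16).", bits))
  }
  micrograph(raw, pixel_size_um = pixel_size_um, bit_depth = as.integer(bits),
             channel_label = channel_label)
}

#' Write a micrograph to TIFF
#'
#' @param img A [micrograph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  maxval <- 2^attr(img, "bit_depth") - 1
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / maxval, path,
                  bits.per.sample = attr(img, "bit_depth"),
                  compression = "none")
  invisible(path)
}

#' Polygonal region of interest
#'
#' Vertices are `(x, y)` pixel coordinates (`x` = column, `y` = row, 0-based
#' pixel centers), the polygon being implicitly closed. It must be simple
#' (non-self-intersecting) with at least three vertices.
#'
#' @param name Region name (e.g. `"cortex"`).
#' @param vertices Two-column numeric matrix (or data frame) of x, y.
#' @return An `roi` object.
#' @export
roi <- function(name, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) abort("`vertices` needs two columns (x, y).")
  if (nrow(vertices) < 3L) abort("an ROI polygon needs at least 3 vertices.")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (!is_simple_polygon(vertices)) {
    abort(sprintf("ROI '%s' is self-intersecting.", name))
  }
  structure(list(name = as.character(name), vertices = vertices),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> '%s', %d vertices\n", x$name, nrow(x$vertices)))
  invisible(x)
}

#' Axis-aligned rectangular ROI
#'
#' Convenience constructor; `roi_rect(name, 0, 0, w, h)` spans the pixel
#' extent of a `w` x `h` image (vertex coordinates run from -0.5 to
#' `w - 0.5` so that every pixel center is strictly interior).
#'
#' @param name Region name.
#' @param x0,y0 Top-left corner, in pixel units counted from the top-left
#'   pixel *extent* (0 = left/top edge of pixel 0).
#' @param width,height Extent in pixels.
#' @return An `roi`.
#' @export
roi_rect <- function(name, x0, y0, width, height) {
  roi(name, cbind(x = c(x0, x0 + width, x0 + width, x0) - 0.5,
                  y = c(y0, y0, y0 + height, y0 + height) - 0.5))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip edges sharing a vertex (adjacent, incl. wrap-around pair)
      if (j == i + 1L || (i == 1L && j == n)) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Read / write ROI collections as JSON
#'
#' Schema: `{"rois": [{"name": "...", "vertices_px": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_rois()`: a named list of [roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$rois)) abort("ROI JSON must have a top-level 'rois' array.")
  out <- lapply(doc$rois, function(r) {
    v <- do.call(rbind, lapply(r$vertices_px, function(p) {
      as.numeric(unlist(p))
    }))
    roi(r$name, v)
  })
  names(out) <- vapply(out, function(r) r$name, character(1))
  out
}

#' @param rois A list of [roi()] objects.
#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    list(name = r$name,
         vertices_px = lapply(seq_len(nrow(r$vertices)),
                              function(i) unname(r$vertices[i, ])))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Physical area of an ROI
#'
#' Shoelace polygon area in pixel units, scaled by the squared pixel size:
#' `area_mm2 = |shoelace| * pixel_size_um^2 / 1e6`.
#'
#' @param roi An [roi()].
#' @param pixel_size_um Micrometres per pixel.
#' @return Area in square millimetres.
#' @export
roi_area_mm2 <- function(roi, pixel_size_um) {
  stopifnot(inherits(roi, "roi"), pixel_size_um > 0)
  v <- roi$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area_px <- abs(sum(x * yn - xn * y)) / 2
  if (area_px <= 0) abort(sprintf("ROI '%s' has zero area.", roi$name))
  area_px * pixel_size_um^2 / 1e6
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray casting; points exactly on an edge follow the half-open
#' ray-cast convention (left/top edges inclusive for axis-aligned
#' rectangles).
#'
#' @param px,py Point coordinates.
#' @param vertices Two-column vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i]
      inside <- xor(inside, cross & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterize an ROI to a pixel mask
#'
#' A pixel belongs to the mask iff its center (0-based integer coordinates)
#' passes the even-odd point-in-polygon test.
#'
#' @param roi An [roi()].
#' @param image_dim `c(n_rows, n_cols)` of the target image.
#' @return Logical matrix of that shape.
#' @export
rasterize_roi <- function(roi, image_dim) {
  stopifnot(inherits(roi, "roi"), length(image_dim) == 2L)
  nr <- image_dim[1]; nc <- image_dim[2]
  v <- roi$vertices
  if (min(v[, 1]) < -0.5 || max(v[, 1]) > nc - 0.5 ||
      min(v[, 2]) < -0.5 || max(v[, 2]) > nr - 0.5) {
    abort(sprintf("ROI '%s' extends outside the %d x %d image.",
                  roi$name, nr, nc))
  }
  px <- rep(0:(nc - 1), each = nr)
  py <- rep(0:(nr - 1), times = nc)
  matrix(point_in_polygon(px, py, v), nrow = nr, ncol = nc)
}
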