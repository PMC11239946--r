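#' Adaptive (local mean) threshold
#'
#' Binarizes a micrograph against its local neighbourhood: a pixel is
#' foreground iff its intensity exceeds the mean over the surrounding
#' `window_px` x `window_px` square plus `offset` grey levels. Borders are
#' handled by symmetric reflection padding. The local statistic suppresses
#' slowly varying background autofluorescence that defeats any global
#' cutoff.
#'
#' @param img A [micrograph()] (or plain integer matrix).
#' @param window_px Odd window side length, `>= 3` and at most the smaller
#'   image dimension. The default (`NULL`) uses 101 px clamped to the image:
#'   the window must comfortably exceed the largest expected deposit
#'   (plaques reach ~20 um = 40 px at the default calibration), otherwise
#'   the object itself dominates its own local mean and bright interiors
#'   fall below threshold.
#' @param offset Grey levels added to the local mean. The default, 10 on an
#'   8-bit scale, is rescaled by 257 for 16-bit images.
#' @return A logical `binary_mask` matrix with a `provenance` attribute
#'   recording the parameters.
#' @export
adaptive_threshold <- function(img, window_px = NULL, offset = NULL) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(window_px)) {
    window_px <- min(101L, min(nr, nc))
    if (window_px %% 2L == 0L) window_px <- window_px - 1L
  }
  if (length(window_px) != 1L || window_px %% 2 == 0 || window_px < 3 ||
      window_px > min(nr, nc)) {
    abort("`window_px` must be odd, >= 3 and <= the smaller image dimension.")
  }
  if (is.null(offset)) {
    bits <- attr(img, "bit_depth")
    offset <- if (!is.null(bits) && bits == 16L) 10 * 257 else 10
  }
  if (offset < 0) abort("`offset` must be >= 0.")
  w <- as.integer(window_px)
  k <- (w - 1L) %/% 2L
  ridx <- c(k:1, 1:nr, nr:(nr - k + 1L))
  cidx <- c(k:1, 1:nc, nc:(nc - k + 1L))
  p <- m[ridx, cidx]
  storage.mode(p) <- "double"  # keep the summed-area table exact, no overflow
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  i <- 1:nr; j <- 1:nc
  winsum <- s[i + w, j + w, drop = FALSE] - s[i, j + w, drop = FALSE] -
    s[i + w, j, drop = FALSE] + s[i, j, drop = FALSE]
  mask <- m > winsum / (w * w) + offset
  binary_mask(mask, provenance = list(op = "adaptive_threshold",
                                      window_px = w, offset = offset))
}

binary_mask <- function(mask, provenance = list()) {
  structure(mask, provenance = provenance,
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.2f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

shift_logical <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (dy > nr - 1 || dy < -(nr - 1) || dx > nc - 1 || dx < -(nc - 1)) {
    return(out)
  }
  sr <- max(1, 1 + dy):min(nr, nr + dy)
  sc <- max(1, 1 + dx):min(nc, nc + dx)
  out[sr - dy, sc - dx] <- m[sr, sc]
  out
}

erode_disk <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_logical(mask, -off$dy[i], -off$dx[i], fill = FALSE)
  }
  out
}

dilate_disk <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_logical(mask, off$dy[i], off$dx[i], fill = FALSE)
  }
  out
}

#' Morphological opening with a disk
#'
#' Erosion followed by dilation with the discrete disk
#' `{(dx, dy) : dx^2 + dy^2 <= r^2}`. Removes connected foreground smaller
#' than the disk while leaving larger structures essentially intact; pixels
#' outside the image are treated as background. `radius_px = 0` is the
#' identity.
#'
#' @param mask A logical mask (e.g. from [adaptive_threshold()]).
#' @param radius_px Disk radius in pixels, `>= 0`.
#' @return A `binary_mask`, a subset of the input.
#' @export
morphological_opening <- function(mask, radius_px = 1L) {
  if (radius_px < 0) abort("`radius_px` must be >= 0.")
  prov <- attr(mask, "provenance")
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  if (radius_px > 0) m <- dilate_disk(erode_disk(m, radius_px), radius_px)
  binary_mask(m, provenance = c(prov, list(opening_radius_px = radius_px)))
}

#' Tissue mask: adaptive threshold then opening
#'
#' The two-step mask the quantification pipeline segments deposits from:
#' local-mean adaptive thresholding to beat uneven background, then a
#' morphological opening to clean speckle noise.
#'
#' @inheritParams adaptive_threshold
#' @param opening_radius_px Disk radius for the opening.
#' @return A `binary_mask`.
#' @export
tissue_mask <- function(img, window_px = NULL, offset = NULL,
                        opening_radius_px = 1L) {
  morphological_opening(adaptive_threshold(img, window_px, offset),
                        radius_px = opening_radius_px)
}

#' Label connected foreground components
#'
#' Two foreground pixels share a label iff they are connected under the
#' chosen connectivity. Labels run 1..N in raster-scan order of each
#' component's first pixel, so the labelling is deterministic.
#'
#' @param mask Logical mask.
#' @param connectivity 4 or 8 (default 8, conventional for blob detection).
#' @return A `labeled_objects` object: list with `labels` (integer matrix),
#'   `n`, and `connectivity`.
#' @export
label_objects <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  lab <- cpp_label_components(m, as.integer(connectivity))
  structure(list(labels = lab, n = attr(lab, "n"),
                 connectivity = as.integer(connectivity)),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d objects (%d-connectivity), %d x %d px\n",
              x$n, x$connectivity, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Drop objects below a pixel-area floor
#'
#' Removes labelled components with fewer than `min_area_px` pixels and
#' recompacts the surviving labels to 1..N' preserving order. The default
#' (4 px) removes single-pixel noise while keeping 2 um deposits at the
#' default 0.5 um/px calibration (~12 px).
#'
#' @param objs A `labeled_objects`.
#' @param min_area_px Minimum pixel count, `>= 1`.
#' @return A `labeled_objects`.
#' @export
filter_small <- function(objs, min_area_px = 4L) {
  stopifnot(inherits(objs, "labeled_objects"))
  if (min_area_px < 1) abort("`min_area_px` must be >= 1.")
  if (objs$n == 0L || min_area_px == 1L) return(objs)
  sizes <- tabulate(objs$labels[objs$labels > 0L], nbins = objs$n)
  keep <- sizes >= min_area_px
  remap <- integer(objs$n)
  remap[keep] <- seq_len(sum(keep))
  lab <- objs$labels
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  structure(list(labels = lab, n = sum(keep),
                 connectivity = objs$connectivity),
            class = "labeled_objects")
}
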