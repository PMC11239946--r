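#' Central moments of a pixel set
#'
#' Returns `mu00` (pixel count) and the second central moments `mu20`,
#' `mu02`, `mu11` about the centroid, with the unit-square correction:
#' each pixel is treated as a 1 x 1 square, contributing variance 1/12 per
#' axis. The correction keeps single pixels and thin bars well defined
#' (no 0/0) and matches the continuous-shape limit. `x` is the column
#' axis, `y` the row axis.
#'
#' @param x,y Pixel-center coordinates (0-based; any common offset works,
#'   the moments are translation invariant).
#' @return Named numeric vector `mu00, mu20, mu02, mu11`.
#' @export
central_moments <- function(x, y) {
  n <- length(x)
  if (n == 0L) abort("empty pixel set.")
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  c(mu00 = n,
    mu20 = sum(dx * dx) + n / 12,
    mu02 = sum(dy * dy) + n / 12,
    mu11 = sum(dx * dy))
}

ecc_from_moments <- function(mu) {
  a <- mu[["mu20"]] / mu[["mu00"]]
  c_ <- mu[["mu02"]] / mu[["mu00"]]
  b <- mu[["mu11"]] / mu[["mu00"]]
  disc <- sqrt((a - c_)^2 + 4 * b * b)
  l1 <- (a + c_ + disc) / 2
  l2 <- (a + c_ - disc) / 2
  sqrt(max(0, 1 - l2 / l1))
}

#' Eccentricity of a pixel set
#'
#' `sqrt(1 - lambda2/lambda1)` of the second-central-moment ellipse
#' (eigenvalues `lambda1 >= lambda2` of the covariance matrix): 0 for a
#' disk, approaching 1 for a line. With the unit-square moment correction
#' `lambda2 > 0` always, so the result is strictly below 1 for any finite
#' pixel set.
#'
#' @inheritParams central_moments
#' @return Eccentricity in `[0, 1)`.
#' @export
eccentricity <- function(x, y) {
  ecc_from_moments(central_moments(x, y))
}

#' Measure labelled deposits in physical units
#'
#' One row per labelled component: pixel count, area
#' (`pixel_count * pixel_size_um^2`), centroid in micrometres (image frame,
#' x = column axis, y = row axis, origin at the top-left pixel center),
#' equivalent diameter `2*sqrt(area/pi)` (the circle of equal area), and
#' moment eccentricity. When `rois` are given each object is assigned to
#' the ROI containing its centroid (objects straddling a boundary are
#' counted once); a centroid in no ROI gets `roi_name = NA` and is excluded
#' from region summaries but kept in the table.
#'
#' @param objs A `labeled_objects` from [label_objects()].
#' @param pixel_size_um Micrometres per pixel.
#' @param rois Optional list of [roi()] objects.
#' @return A tibble with columns `label`, `roi_name`, `pixel_count`,
#'   `area_um2`, `equivalent_diameter_um`, `eccentricity`,
#'   `centroid_x_um`, `centroid_y_um`, `class`, `nearest_nucleus_um`.
#' @export
measure_objects <- function(objs, pixel_size_um, rois = NULL) {
  stopifnot(inherits(objs, "labeled_objects"), pixel_size_um > 0)
  empty <- tibble(label = integer(), roi_name = character(),
                  pixel_count = integer(), area_um2 = double(),
                  equivalent_diameter_um = double(), eccentricity = double(),
                  centroid_x_um = double(), centroid_y_um = double(),
                  class = character(), nearest_nucleus_um = double())
  if (objs$n == 0L) return(empty)
  lab <- objs$labels
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  # doubles: products like x*x summed over an object overflow integers
  x <- as.numeric((idx - 1L) %/% nr)   # 0-based column
  y <- as.numeric((idx - 1L) %% nr)    # 0-based row
  n <- tabulate(lv, nbins = objs$n)
  sx <- unname(rowsum(x, lv)[, 1]); sy <- unname(rowsum(y, lv)[, 1])
  cx <- sx / n; cy <- sy / n
  sxx <- unname(rowsum(x * x, lv)[, 1])
  syy <- unname(rowsum(y * y, lv)[, 1])
  sxy <- unname(rowsum(x * y, lv)[, 1])
  mu20 <- (sxx - n * cx^2 + n / 12) / n
  mu02 <- (syy - n * cy^2 + n / 12) / n
  mu11 <- (sxy - n * cx * cy) / n
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  ecc <- sqrt(pmax(0, 1 - l2 / l1))
  area <- n * pixel_size_um^2
  roi_name <- rep(NA_character_, objs$n)
  if (!is.null(rois)) {
    for (r in rois) {
      inside <- point_in_polygon(cx, cy, r$vertices)
      roi_name[inside & is.na(roi_name)] <- r$name
    }
  }
  tibble(label = seq_len(objs$n),
         roi_name = roi_name,
         pixel_count = as.integer(n),
         area_um2 = area,
         equivalent_diameter_um = 2 * sqrt(area / pi),
         eccentricity = ecc,
         centroid_x_um = cx * pixel_size_um,
         centroid_y_um = cy * pixel_size_um,
         class = "unclassified",
         nearest_nucleus_um = NA_real_)
}

#' Deposit density per square millimetre
#'
#' The burden statistic: object count divided by the ROI area.
#'
#' @param n_objects Object count.
#' @param roi_area_mm2 ROI area in mm^2 (> 0).
#' @return Objects per mm^2.
#' @export
density_per_mm2 <- function(n_objects, roi_area_mm2) {
  if (any(roi_area_mm2 <= 0)) abort("`roi_area_mm2` must be > 0.")
  n_objects / roi_area_mm2
}
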