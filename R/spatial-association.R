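#' Detect nuclei in a DAPI-style channel
#'
#' Segments the nuclei channel with the same adaptive-threshold /
#' opening / labelling chain as the deposit channel, then keeps components
#' whose equivalent diameter falls in a nucleus-sized window (default
#' 4-15 um), excluding speckle below and deposit bleed-through above it.
#'
#' @param nuclei_channel A [micrograph()].
#' @param min_diameter_um,max_diameter_um Equivalent-diameter window.
#' @param window_px,offset,opening_radius_px Segmentation parameters, see
#'   [tissue_mask()].
#' @return A `nucleus_set` tibble: `nucleus_id`, `x_um`, `y_um`,
#'   `equivalent_diameter_um`; mean nucleus radius attached as attribute
#'   `"mean_radius_um"`.
#' @export
detect_nuclei <- function(nuclei_channel, min_diameter_um = 4,
                          max_diameter_um = 15, window_px = NULL,
                          offset = NULL, opening_radius_px = 1L) {
  mask <- tissue_mask(nuclei_channel, window_px, offset, opening_radius_px)
  objs <- label_objects(mask)
  meas <- measure_objects(objs, pixel_size(nuclei_channel))
  keep <- dplyr::filter(meas,
                        .data$equivalent_diameter_um >= min_diameter_um,
                        .data$equivalent_diameter_um <= max_diameter_um)
  out <- tibble(nucleus_id = seq_len(nrow(keep)),
                x_um = keep$centroid_x_um,
                y_um = keep$centroid_y_um,
                equivalent_diameter_um = keep$equivalent_diameter_um)
  attr(out, "mean_radius_um") <-
    if (nrow(out)) mean(out$equivalent_diameter_um) / 2 else NA_real_
  class(out) <- c("nucleus_set", class(out))
  out
}

#' Nucleus set from known centroids
#'
#' @param x_um,y_um Nucleus centroid coordinates in micrometres.
#' @param mean_radius_um Optional mean nucleus radius.
#' @return A `nucleus_set` tibble.
#' @export
nucleus_set <- function(x_um, y_um, mean_radius_um = NA_real_) {
  out <- tibble(nucleus_id = seq_along(x_um), x_um = x_um, y_um = y_um,
                equivalent_diameter_um = 2 * mean_radius_um)
  attr(out, "mean_radius_um") <- mean_radius_um
  class(out) <- c("nucleus_set", class(out))
  out
}

#' Distance from each object to its nearest nucleus
#'
#' Minimum Euclidean centroid-to-centroid distance, in micrometres.
#'
#' @param x_um,y_um Object centroid coordinates.
#' @param nuclei A `nucleus_set` (must be non-empty).
#' @return Numeric vector of distances.
#' @export
nearest_nucleus_distance <- function(x_um, y_um, nuclei) {
  if (nrow(nuclei) == 0L) {
    abort("`nuclei` is empty: no nearest-nucleus distance is defined.")
  }
  if (length(x_um) == 0L) return(numeric())
  d2 <- outer(x_um, nuclei$x_um, "-")^2 + outer(y_um, nuclei$y_um, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Classify deposit-nucleus association
#'
#' A deposit is perinuclear iff its nearest-nucleus distance is at most
#' `cutoff_um` (boundary inclusive), else extracellular. The default
#' 10 um is roughly one neuronal-soma radius beyond the nucleus center —
#' an explicit operationalisation, since "associated with the nucleus" is
#' inherently a visual call.
#'
#' @param distance_um Non-negative distances.
#' @param cutoff_um Positive cutoff (default 10).
#' @return Character vector, `"perinuclear"` or `"extracellular"`.
#' @export
classify_association <- function(distance_um, cutoff_um = 10) {
  if (cutoff_um <= 0) abort("`cutoff_um` must be > 0.")
  if (any(distance_um < 0)) abort("distances must be >= 0.")
  ifelse(distance_um <= cutoff_um, "perinuclear", "extracellular")
}

#' Associate measured deposits with nuclei
#'
#' Fills `nearest_nucleus_um` and an `association` column on a measured
#' object table.
#'
#' @param objects Tibble from [measure_objects()] (classes filled).
#' @param nuclei A `nucleus_set`.
#' @param cutoff_um See [classify_association()].
#' @return `objects` with `nearest_nucleus_um` and `association` columns.
#' @export
associate_deposits <- function(objects, nuclei, cutoff_um = 10) {
  if (nrow(objects) == 0L) {
    objects$association <- character()
    return(objects)
  }
  objects$nearest_nucleus_um <- nearest_nucleus_distance(
    objects$centroid_x_um, objects$centroid_y_um, nuclei)
  objects$association <- classify_association(objects$nearest_nucleus_um,
                                              cutoff_um)
  objects
}

#' Per-class summary of deposit-nucleus association
#'
#' For each deposit class: object count, fraction perinuclear and median
#' nearest-nucleus distance. Classes absent from the data are reported
#' with `n = 0` and undefined (NA) fraction and median when listed in
#' `classes`.
#'
#' @param objects Tibble with `class`, `nearest_nucleus_um` and
#'   `association` columns (see [associate_deposits()]).
#' @param classes Classes to report (default those present).
#' @return An `association_summary` tibble: `class`, `n`,
#'   `fraction_perinuclear`, `median_distance_um`.
#' @export
association_summary <- function(objects, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(objects$class))
  out <- purrr::map_dfr(classes, function(cl) {
    o <- objects[objects$class == cl, , drop = FALSE]
    tibble(class = cl,
           n = nrow(o),
           fraction_perinuclear =
             if (nrow(o)) mean(o$association == "perinuclear") else NA_real_,
           median_distance_um =
             if (nrow(o)) median(o$nearest_nucleus_um) else NA_real_)
  })
  class(out) <- c("association_summary", class(out))
  out
}
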