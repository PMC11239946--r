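#' Specification of a synthetic micrograph scene
#'
#' Describes a calibrated two-channel field (deposits + nuclei) with
#' planted ground truth emulating amyloid staining in transgenic mouse
#' brain sections: a population of small perinuclear puncta (soluble
#' oligomers, log-normal equivalent diameter, geometric mean 2 um) and a
#' population of large irregular blobs (plaques, geometric mean 14 um,
#' elongated so rasterized eccentricity averages ~0.5) placed away from
#' nuclei, on a flat autofluorescent background with additive Gaussian
#' noise.
#'
#' Diameter draws are truncated: oligomers at `>= oligomer_min_diameter_um`
#' (default 1.6 um, ~3 pixels at the default calibration — smaller spots
#' are below the practical resolution of the imaging this emulates and
#' would be erased by the default radius-1 opening), plaques at
#' `<= plaque_max_diameter_um` (default 20 um, the reported plaque size in
#' this mouse model, which also keeps every deposit small relative to the
#' default adaptive-threshold window so plaque interiors stay above the
#' local mean plus offset).
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel (default 0.5; the source
#'   acquisition scale is unknown, this is a documented free choice).
#' @param rois List of entries made with [scene_roi()]; defaults to a
#'   single full-frame field at 100 oligomers and 25 plaques per mm^2.
#' @param oligomer_diameter_um,plaque_diameter_um Geometric mean
#'   equivalent diameters of the two populations.
#' @param diameter_gsd Geometric SD shared by both log-normal diameter
#'   distributions (default 1.3).
#' @param plaque_axis_ratio Length-2 range of the minor/major axis ratio
#'   drawn uniformly for plaques (default `c(0.75, 0.97)`, calibrated so
#'   mean rasterized eccentricity is ~0.5); oligomers are circular.
#' @param nuclei_density Nuclei per mm^2 (default 150, a sparse single
#'   optical section).
#' @param nucleus_diameter_um Rendered nucleus diameter (default 8).
#' @param perinuclear_offset_um Center-to-center distance at which each
#'   oligomer is planted next to a nucleus (default 6: nucleus radius
#'   plus ~an oligomer diameter).
#' @param foreground_intensity,background_intensity,noise_sd Grey levels
#'   (defaults 6000 / 1000 / 500 on the 16-bit scale).
#' @param bit_depth 8 or 16.
#' @param seed Integer RNG seed; the whole scene is a pure function of the
#'   spec including this seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_height_px = 800L, image_width_px = 800L,
                       pixel_size_um = 0.5, rois = NULL,
                       oligomer_diameter_um = 2, plaque_diameter_um = 14,
                       diameter_gsd = 1.3,
                       oligomer_min_diameter_um = 1.6,
                       plaque_max_diameter_um = 20,
                       plaque_axis_ratio = c(0.75, 0.97),
                       nuclei_density = 150, nucleus_diameter_um = 8,
                       perinuclear_offset_um = 6,
                       foreground_intensity = 6000L,
                       background_intensity = 1000L,
                       noise_sd = 500, bit_depth = 16L, seed = 1L) {
  if (is.null(rois)) {
    rois <- list(scene_roi(
      roi_rect("field", 0, 0, image_width_px, image_height_px),
      oligomer_density = 100, plaque_density = 25))
  }
  spec <- list(image_height_px = as.integer(image_height_px),
               image_width_px = as.integer(image_width_px),
               pixel_size_um = pixel_size_um, rois = rois,
               oligomer_diameter_um = oligomer_diameter_um,
               plaque_diameter_um = plaque_diameter_um,
               diameter_gsd = diameter_gsd,
               oligomer_min_diameter_um = oligomer_min_diameter_um,
               plaque_max_diameter_um = plaque_max_diameter_um,
               plaque_axis_ratio = plaque_axis_ratio,
               nuclei_density = nuclei_density,
               nucleus_diameter_um = nucleus_diameter_um,
               perinuclear_offset_um = perinuclear_offset_um,
               foreground_intensity = as.integer(foreground_intensity),
               background_intensity = as.integer(background_intensity),
               noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

#' ROI entry of a scene specification
#'
#' @param roi An [roi()] polygon (pixel coordinates).
#' @param oligomer_density,plaque_density Target densities, objects/mm^2
#'   (>= 0). Planted counts are exactly `round(density * area_mm2)`.
#' @return A `scene_roi` list.
#' @export
scene_roi <- function(roi, oligomer_density, plaque_density) {
  stopifnot(inherits(roi, "roi"),
            oligomer_density >= 0, plaque_density >= 0)
  structure(list(roi = roi, oligomer_density = oligomer_density,
                 plaque_density = plaque_density), class = "scene_roi")
}

validate_scene_spec <- function(spec) {
  with(spec, {
    stopifnot(image_height_px > 0, image_width_px > 0, pixel_size_um > 0,
              oligomer_diameter_um > 0, plaque_diameter_um > 0,
              diameter_gsd >= 1, oligomer_min_diameter_um > 0,
              plaque_max_diameter_um > plaque_diameter_um,
              nuclei_density >= 0,
              nucleus_diameter_um > 0, perinuclear_offset_um > 0,
              noise_sd >= 0, bit_depth %in% c(8L, 16L),
              length(plaque_axis_ratio) == 2,
              plaque_axis_ratio[1] > 0, plaque_axis_ratio[2] <= 1,
              plaque_axis_ratio[1] <= plaque_axis_ratio[2])
    if (foreground_intensity <= background_intensity) {
      abort("foreground intensity must exceed background intensity.")
    }
    if (foreground_intensity > 2^bit_depth - 1) {
      abort("foreground intensity exceeds the bit-depth range.")
    }
  })
  for (sr in spec$rois) {
    stopifnot(inherits(sr, "scene_roi"))
    v <- sr$roi$vertices
    if (min(v[, 1]) < -0.5 || max(v[, 1]) > spec$image_width_px - 0.5 ||
        min(v[, 2]) < -0.5 || max(v[, 2]) > spec$image_height_px - 0.5) {
      abort(sprintf("ROI '%s' lies outside the image bounds.", sr$roi$name))
    }
  }
  invisible(spec)
}

#' The four-region preset mirroring reported 5XFAD burden
#'
#' Four square ROIs (cortex, hippocampus, hypothalamus, thalamus) in a
#' 2 x 2 layout, each `roi_side_um` on a side, with total deposit
#' densities set to the reported regional values (89.72, 38.87, 170.90
#' and 122.44 objects/mm^2) split 80/20 between oligomers and plaques.
#'
#' @param roi_side_um Side of each square ROI, micrometres (default 500,
#'   i.e. 0.25 mm^2 per region).
#' @param oligomer_fraction Fraction of each region's density planted as
#'   oligomers (default 0.8).
#' @param seed RNG seed.
#' @param ... Passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
scene_spec_5xfad <- function(roi_side_um = 500, oligomer_fraction = 0.8,
                             seed = 1L, ...) {
  px <- 0.5
  side <- round(roi_side_um / px)
  margin <- 60L
  dens <- c(cortex = 89.72, hippocampus = 38.87,
            hypothalamus = 170.90, thalamus = 122.44)
  size <- as.integer(2L * side + 3L * margin)
  pos <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  rois <- purrr::map2(names(dens), pos, function(nm, p) {
    x0 <- margin + p[1] * (side + margin)
    y0 <- margin + p[2] * (side + margin)
    scene_roi(roi_rect(nm, x0, y0, side, side),
              oligomer_density = dens[[nm]] * oligomer_fraction,
              plaque_density = dens[[nm]] * (1 - oligomer_fraction))
  })
  scene_spec(image_height_px = size, image_width_px = size,
             pixel_size_um = px, rois = rois, seed = seed, ...)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    d <- rlnorm(n, meanlog, sdlog)
    out <- c(out, d[d >= lower & d <= upper])
    guard <- guard + 1
    if (guard > 1000) abort("truncated log-normal sampling failed.")
  }
  out[seq_len(n)]
}

sample_in_polygon <- function(vertices) {
  bx <- range(vertices[, 1]); by <- range(vertices[, 2])
  repeat {
    p <- c(runif(1, bx[1], bx[2]), runif(1, by[1], by[2]))
    if (point_in_polygon(p[1], p[2], vertices)) return(p)
  }
}

#' Plan a synthetic scene: placement and ground truth
#'
#' Places nuclei and both deposit populations by rejection sampling under
#' hard geometric constraints, deterministically for a fixed seed:
#' * per-ROI counts are exactly `round(density x area_mm2)` (no Poisson
#'   variation, so recovery tests have exact targets);
#' * every oligomer center sits exactly `perinuclear_offset_um` from some
#'   nucleus center in its ROI;
#' * every plaque center is at least `3 x nucleus_diameter_um` from every
#'   nucleus center;
#' * no two deposit objects overlap (bounding-circle rule with a 3-pixel
#'   clearance, so rasterized objects stay disconnected), and every
#'   object lies wholly inside the image.
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Rejection-sampling attempts allowed per planted
#'   item before giving up with an error naming the ROI.
#' @return A `ground_truth`: list with tibbles `objects` (class,
#'   roi_name, center, semi-axes, orientation, true equivalent diameter
#'   and eccentricity) and `nuclei`, plus the seed.
#' @export
plan_scene <- function(spec, max_attempts = 5000L) {
  validate_scene_spec(spec)
  withr::with_seed(spec$seed, plan_scene_impl(spec, max_attempts))
}

plan_scene_impl <- function(spec, max_attempts) {
  ps <- spec$pixel_size_um
  w_um <- spec$image_width_px * ps
  h_um <- spec$image_height_px * ps
  nuc_r <- spec$nucleus_diameter_um / 2
  clearance <- 3 * ps
  nuclei <- list()
  objects <- list()
  obj_x <- obj_y <- obj_r <- numeric(0)     # accepted-object circles
  nuc_x <- nuc_y <- numeric(0)
  place_fail <- function(what, roi_name) {
    abort(sprintf(
      "could not place %s in ROI '%s' after %d attempts: density too high for the constraints.",
      what, roi_name, max_attempts))
  }
  # phase 1: all nuclei, so plaque exclusion zones are complete before any
  # deposit is placed
  for (sr in spec$rois) {
    v_um <- sr$roi$vertices * ps
    area <- roi_area_mm2(sr$roi, ps)
    n_nuc <- round(spec$nuclei_density * area)
    for (i in seq_len(n_nuc)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- sample_in_polygon(v_um)
        if (p[1] - nuc_r < 0 || p[1] + nuc_r > w_um - ps ||
            p[2] - nuc_r < 0 || p[2] + nuc_r > h_um - ps) next
        if (length(nuc_x) &&
            min((nuc_x - p[1])^2 + (nuc_y - p[2])^2) <
            (spec$nucleus_diameter_um + clearance)^2) next
        ok <- TRUE; break
      }
      if (!ok) place_fail("a nucleus", sr$roi$name)
      nuc_x <- c(nuc_x, p[1]); nuc_y <- c(nuc_y, p[2])
      nuclei[[length(nuclei) + 1L]] <-
        tibble(roi_name = sr$roi$name, x_um = p[1], y_um = p[2])
    }
  }
  nuc_roi <- vapply(nuclei, function(n) n$roi_name, character(1))
  # phase 2: deposits
  for (sr in spec$rois) {
    v_um <- sr$roi$vertices * ps
    area <- roi_area_mm2(sr$roi, ps)
    roi_nuc_x <- nuc_x[nuc_roi == sr$roi$name]
    roi_nuc_y <- nuc_y[nuc_roi == sr$roi$name]
    # --- plaques ---
    n_pla <- round(sr$plaque_density * area)
    meanlog_p <- log(spec$plaque_diameter_um)
    sdlog <- log(spec$diameter_gsd)
    for (i in seq_len(n_pla)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        d <- rtrunc_lnorm(1, meanlog_p, sdlog,
                          upper = spec$plaque_max_diameter_um)
        q <- runif(1, spec$plaque_axis_ratio[1], spec$plaque_axis_ratio[2])
        a <- d / (2 * sqrt(q)); b <- d * sqrt(q) / 2
        theta <- runif(1, 0, pi)
        p <- sample_in_polygon(v_um)
        if (p[1] - a < 0 || p[1] + a > w_um - ps ||
            p[2] - a < 0 || p[2] + a > h_um - ps) next
        if (length(nuc_x) &&
            min((nuc_x - p[1])^2 + (nuc_y - p[2])^2) <
            (3 * spec$nucleus_diameter_um)^2) next
        if (length(obj_x) &&
            min(sqrt((obj_x - p[1])^2 + (obj_y - p[2])^2) -
                obj_r - a) < clearance) next
        ok <- TRUE; break
      }
      if (!ok) place_fail("a plaque", sr$roi$name)
      obj_x <- c(obj_x, p[1]); obj_y <- c(obj_y, p[2]); obj_r <- c(obj_r, a)
      objects[[length(objects) + 1L]] <- tibble(
        class = "plaque", roi_name = sr$roi$name,
        x_um = p[1], y_um = p[2], semi_major_um = a, semi_minor_um = b,
        orientation_rad = theta,
        equivalent_diameter_um = 2 * sqrt(a * b),
        eccentricity = sqrt(1 - (b / a)^2))
    }
    # --- oligomers, planted adjacent to nuclei ---
    n_oli <- round(sr$oligomer_density * area)
    meanlog_o <- log(spec$oligomer_diameter_um)
    if (n_oli > 0 && length(roi_nuc_x) == 0L) {
      abort(sprintf(
        "ROI '%s' needs oligomers but holds no nuclei; raise nuclei_density.",
        sr$roi$name))
    }
    for (i in seq_len(n_oli)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        d <- rtrunc_lnorm(1, meanlog_o, sdlog,
                          lower = spec$oligomer_min_diameter_um)
        a <- d / 2
        j <- sample.int(length(roi_nuc_x), 1)
        ang <- runif(1, 0, 2 * pi)
        p <- c(roi_nuc_x[j] + spec$perinuclear_offset_um * cos(ang),
               roi_nuc_y[j] + spec$perinuclear_offset_um * sin(ang))
        if (!point_in_polygon(p[1], p[2], v_um)) next
        if (p[1] - a < 0 || p[1] + a > w_um - ps ||
            p[2] - a < 0 || p[2] + a > h_um - ps) next
        if (length(obj_x) &&
            min(sqrt((obj_x - p[1])^2 + (obj_y - p[2])^2) -
                obj_r - a) < clearance) next
        ok <- TRUE; break
      }
      if (!ok) place_fail("an oligomer", sr$roi$name)
      obj_x <- c(obj_x, p[1]); obj_y <- c(obj_y, p[2]); obj_r <- c(obj_r, a)
      objects[[length(objects) + 1L]] <- tibble(
        class = "oligomer", roi_name = sr$roi$name,
        x_um = p[1], y_um = p[2], semi_major_um = a, semi_minor_um = a,
        orientation_rad = 0,
        equivalent_diameter_um = d, eccentricity = 0)
    }
  }
  empty_obj <- tibble(class = character(), roi_name = character(),
                      x_um = double(), y_um = double(),
                      semi_major_um = double(), semi_minor_um = double(),
                      orientation_rad = double(),
                      equivalent_diameter_um = double(),
                      eccentricity = double())
  empty_nuc <- tibble(roi_name = character(), x_um = double(),
                      y_um = double())
  structure(list(
    objects = if (length(objects)) dplyr::bind_rows(objects) else empty_obj,
    nuclei = if (length(nuclei)) dplyr::bind_rows(nuclei) else empty_nuc,
    seed = spec$seed), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d objects (%d oligomer, %d plaque), %d nuclei, seed %d\n",
    nrow(x$objects), sum(x$objects$class == "oligomer"),
    sum(x$objects$class == "plaque"), nrow(x$nuclei), x$seed))
  invisible(x)
}

# column-major linear indices of the pixels whose centers fall inside the
# ellipse (boundary counts as inside)
ellipse_indices <- function(nr, nc, cx_px, cy_px, a_px, b_px, theta) {
  wx <- sqrt((a_px * cos(theta))^2 + (b_px * sin(theta))^2)
  wy <- sqrt((a_px * sin(theta))^2 + (b_px * cos(theta))^2)
  if (cx_px - wx < 0 || cx_px + wx > nc - 1 ||
      cy_px - wy < 0 || cy_px + wy > nr - 1) {
    abort("object extends outside the image bounds.")
  }
  cols <- floor(cx_px - wx):ceiling(cx_px + wx)
  rows <- floor(cy_px - wy):ceiling(cy_px + wy)
  dx <- outer(rep(1, length(rows)), cols - cx_px)
  dy <- outer(rows - cy_px, rep(1, length(cols)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  inside <- which(u * u + v * v <= 1)
  ri <- rows[(inside - 1L) %% length(rows) + 1L]
  ci <- cols[(inside - 1L) %/% length(rows) + 1L]
  ci * nr + ri + 1L
}

#' Render a planned scene to calibrated micrographs
#'
#' Rasterizes every planted ellipse (a pixel belongs to an object iff its
#' center lies inside, boundary inclusive) at the foreground intensity on
#' a flat background, then adds independent zero-mean Gaussian noise with
#' sd `noise_sd` and clips to the bit-depth range. Nuclei are rendered as
#' disks on a second channel. `noise_sd = 0` yields noiseless images.
#'
#' @param truth A `ground_truth` from [plan_scene()].
#' @param spec The same [scene_spec()] the truth was planned from.
#' @return List with micrographs `deposits` and `nuclei`.
#' @export
render_scene <- function(truth, spec) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "scene_spec"))
  ps <- spec$pixel_size_um
  nr <- spec$image_height_px; nc <- spec$image_width_px
  base <- matrix(as.numeric(spec$background_intensity), nr, nc)
  obj <- truth$objects
  dep <- base
  idx <- lapply(seq_len(nrow(obj)), function(i) {
    ellipse_indices(nr, nc, obj$x_um[i] / ps, obj$y_um[i] / ps,
                    obj$semi_major_um[i] / ps, obj$semi_minor_um[i] / ps,
                    obj$orientation_rad[i])
  })
  dep[unlist(idx)] <- spec$foreground_intensity
  nuc <- base
  r_px <- spec$nucleus_diameter_um / 2 / ps
  idx <- lapply(seq_len(nrow(truth$nuclei)), function(i) {
    ellipse_indices(nr, nc, truth$nuclei$x_um[i] / ps,
                    truth$nuclei$y_um[i] / ps, r_px, r_px, 0)
  })
  nuc[unlist(idx)] <- spec$foreground_intensity
  maxval <- 2^spec$bit_depth - 1
  render_seed <- (spec$seed %% 1000000000L) + 7919L
  withr::with_seed(render_seed, {
    if (spec$noise_sd > 0) {
      dep <- dep + rnorm(length(dep), 0, spec$noise_sd)
      nuc <- nuc + rnorm(length(nuc), 0, spec$noise_sd)
    }
  })
  clipint <- function(m) {
    m <- round(m)
    m[m < 0] <- 0
    m[m > maxval] <- maxval
    matrix(as.integer(m), nrow(m), ncol(m))
  }
  list(deposits = micrograph(clipint(dep), ps, spec$bit_depth, "deposits"),
       nuclei = micrograph(clipint(nuc), ps, spec$bit_depth, "nuclei"))
}

#' Write / read ground truth as CSV
#'
#' One row per planted object and per nucleus (`record_type` column);
#' nucleus rows leave the shape columns NA. Round-trips losslessly.
#'
#' @param truth A `ground_truth`.
#' @param path CSV path.
#' @return `write_truth()`: `path`, invisibly. `read_truth()`: a
#'   `ground_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- truth$objects
  obj$record_type <- rep("object", nrow(obj))
  nuc <- truth$nuclei
  nuc$record_type <- rep("nucleus", nrow(nuc))
  out <- dplyr::bind_rows(obj, nuc)
  cols <- c("record_type", "class", "roi_name", "x_um", "y_um",
            "semi_major_um", "semi_minor_um", "orientation_rad",
            "equivalent_diameter_um", "eccentricity")
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out <- out[, cols, drop = FALSE]
  out$seed <- rep(truth$seed, nrow(out))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          record_type = "c", class = "c", roi_name = "c",
                          seed = "i", .default = "d"))
  seed <- if (nrow(tb)) tb$seed[1] else NA_integer_
  obj <- tb[tb$record_type == "object",
            c("class", "roi_name", "x_um", "y_um", "semi_major_um",
              "semi_minor_um", "orientation_rad",
              "equivalent_diameter_um", "eccentricity")]
  nuc <- tb[tb$record_type == "nucleus", c("roi_name", "x_um", "y_um")]
  structure(list(objects = as_tibble(obj), nuclei = as_tibble(nuc),
                 seed = seed), class = "ground_truth")
}
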