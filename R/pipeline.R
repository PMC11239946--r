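default_params <- function() {
  list(window_px = NULL, offset = NULL, opening_radius_px = 1L,
       connectivity = 8L, min_area_px = 4L,
       bimodality_floor = 0.75, fallback_cutoff_um = 6,
       association_cutoff_um = 10,
       nucleus_min_diameter_um = 4, nucleus_max_diameter_um = 15)
}

merge_params <- function(params) {
  base <- default_params()
  if (is.null(params)) return(base)
  unknown <- setdiff(names(params), names(base))
  if (length(unknown)) {
    abort(paste("unknown parameter(s):", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(base, params)
}

write_manifest <- function(out_dir, mode, params, inputs, seed = NULL) {
  paths <- as.character(unlist(inputs))
  paths <- paths[file.exists(paths)]
  manifest <- list(
    mode = mode,
    version = as.character(utils::packageVersion("abetamorph")),
    seed = seed,
    parameters = params,
    inputs = inputs,
    input_md5 = if (length(paths)) as.list(tools::md5sum(paths)) else list())
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

with_clean_outputs <- function(out_dir, expr) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  before <- list.files(out_dir, full.names = TRUE)
  tryCatch(expr, error = function(e) {
    created <- setdiff(list.files(out_dir, full.names = TRUE), before)
    unlink(created)
    abort(conditionMessage(e))
  })
}

#' Simulate a scene to disk
#'
#' Plans and renders a [scene_spec()], writing `deposits.tif`,
#' `nuclei.tif`, `truth.csv`, `rois.json` and a run manifest. Fully
#' deterministic per seed: repeated runs are byte-identical.
#'
#' @param spec A [scene_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the truth and file paths.
#' @export
run_simulate <- function(spec, out_dir) {
  with_clean_outputs(out_dir, {
    truth <- plan_scene(spec)
    imgs <- render_scene(truth, spec)
    paths <- list(deposits = file.path(out_dir, "deposits.tif"),
                  nuclei = file.path(out_dir, "nuclei.tif"),
                  truth = file.path(out_dir, "truth.csv"),
                  rois = file.path(out_dir, "rois.json"))
    write_micrograph(imgs$deposits, paths$deposits)
    write_micrograph(imgs$nuclei, paths$nuclei)
    write_truth(truth, paths$truth)
    write_rois(lapply(spec$rois, function(sr) sr$roi), paths$rois)
    spec_plain <- unclass(spec)
    spec_plain$rois <- lapply(spec$rois, function(sr) {
      list(name = sr$roi$name, oligomer_density = sr$oligomer_density,
           plaque_density = sr$plaque_density,
           vertices_px = lapply(seq_len(nrow(sr$roi$vertices)),
                                function(i) unname(sr$roi$vertices[i, ])))
    })
    write_manifest(out_dir, "simulate", spec_plain, paths, seed = spec$seed)
    invisible(list(truth = truth, paths = paths))
  })
}

quantify_micrograph <- function(img, rois, params) {
  mask <- tissue_mask(img, params$window_px, params$offset,
                      params$opening_radius_px)
  objs <- label_objects(mask, params$connectivity)
  objs <- filter_small(objs, params$min_area_px)
  list(mask = mask,
       objects = measure_objects(objs, pixel_size(img), rois))
}

#' Quantify deposit burden on one or more slides
#'
#' The end-to-end measurement: adaptive threshold, opening,
#' connected-component labelling, small-object filtering, per-object
#' morphometrics, ROI assignment by centroid, size classification into
#' oligomer/plaque, and per-region density summary across slides.
#'
#' @param images Named list of deposit-channel [micrograph()]s (names are
#'   slide ids) or a character vector of TIFF paths.
#' @param rois List of [roi()] polygons shared by all slides.
#' @param pixel_size_um Calibration; required when `images` are paths.
#' @param params Named list overriding [segmentation][tissue_mask] and
#'   classification defaults (window_px, offset, opening_radius_px,
#'   connectivity, min_area_px, bimodality_floor, fallback_cutoff_um);
#'   unknown keys are rejected.
#' @param out_dir Optional: write `objects.csv`, `region_summary.csv` and
#'   a manifest there.
#' @return List with tibbles `objects` and `regions`.
#' @export
run_quantify <- function(images, rois, pixel_size_um = NULL,
                         params = list(), out_dir = NULL) {
  params <- merge_params(params)
  if (is.character(images)) {
    if (is.null(pixel_size_um)) {
      abort("`pixel_size_um` is required when images are given as paths.")
    }
    nms <- if (!is.null(names(images))) names(images) else
      tools::file_path_sans_ext(basename(images))
    images <- stats::setNames(
      lapply(images, read_micrograph, pixel_size_um = pixel_size_um), nms)
  }
  if (is.null(names(images)) || any(!nzchar(names(images)))) {
    names(images) <- paste0("slide", seq_along(images))
  }
  ps <- pixel_size(images[[1]])
  objects <- purrr::imap_dfr(images, function(img, id) {
    q <- quantify_micrograph(img, rois, params)
    dplyr::mutate(q$objects, slide_id = id, .before = 1)
  })
  if (nrow(objects) > 0) {
    objects <- classify_deposits(objects,
                                 bimodality_floor = params$bimodality_floor,
                                 fallback_cutoff_um = params$fallback_cutoff_um)
  }
  areas <- vapply(rois, roi_area_mm2, numeric(1), pixel_size_um = ps)
  names(areas) <- vapply(rois, function(r) r$name, character(1))
  regions <- region_summary(objects, areas, slides = names(images))
  if (!is.null(out_dir)) {
    with_clean_outputs(out_dir, {
      readr::write_csv(objects, file.path(out_dir, "objects.csv"))
      readr::write_csv(regions, file.path(out_dir, "region_summary.csv"))
      write_manifest(out_dir, "quantify", params, list())
    })
  }
  list(objects = objects, regions = regions)
}

#' Rank clones from a manifest table
#'
#' @param manifest A data frame (or CSV path) with columns `clone_id`,
#'   `replicate`, `image_path`, `reference_path`.
#' @param pixel_size_um Calibration for the images.
#' @param out_dir Optional: write `ranking.csv` there.
#' @return A `clone_ranking` tibble (see [rank_clones()]).
#' @export
run_rank_clones <- function(manifest, pixel_size_um, out_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  stains <- tibble(
    clone_id = manifest$clone_id,
    replicate = manifest$replicate,
    image = lapply(manifest$image_path, read_micrograph,
                   pixel_size_um = pixel_size_um),
    reference = lapply(manifest$reference_path, read_micrograph,
                       pixel_size_um = pixel_size_um))
  ranking <- rank_clones(stains)
  if (!is.null(out_dir)) {
    with_clean_outputs(out_dir, {
      readr::write_csv(ranking, file.path(out_dir, "ranking.csv"))
      write_manifest(out_dir, "rank-clones", list(), list())
    })
  }
  ranking
}

#' Deposit-nucleus association analysis
#'
#' Quantifies the deposit channel, detects nuclei on the nuclei channel,
#' and classifies each deposit as perinuclear or extracellular by its
#' nearest-nucleus centroid distance.
#'
#' @param deposit_img,nuclei_img [micrograph()]s of the two channels.
#' @param rois List of [roi()] polygons.
#' @param params See [run_quantify()]; also accepts
#'   `association_cutoff_um`, `nucleus_min_diameter_um`,
#'   `nucleus_max_diameter_um`.
#' @param out_dir Optional: write `association.csv` and `summary.json`.
#' @return List with `objects` (distances and association labels),
#'   `nuclei` and `summary` (an `association_summary` tibble).
#' @export
run_associate <- function(deposit_img, nuclei_img, rois = NULL,
                          params = list(), out_dir = NULL) {
  params <- merge_params(params)
  q <- quantify_micrograph(deposit_img, rois, params)
  objects <- q$objects
  if (nrow(objects) > 0) {
    objects <- classify_deposits(objects,
                                 bimodality_floor = params$bimodality_floor,
                                 fallback_cutoff_um = params$fallback_cutoff_um)
  }
  nuclei <- detect_nuclei(nuclei_img,
                          min_diameter_um = params$nucleus_min_diameter_um,
                          max_diameter_um = params$nucleus_max_diameter_um,
                          window_px = params$window_px,
                          offset = params$offset,
                          opening_radius_px = params$opening_radius_px)
  objects <- associate_deposits(objects, nuclei,
                                cutoff_um = params$association_cutoff_um)
  summ <- association_summary(objects, classes = c("oligomer", "plaque"))
  if (!is.null(out_dir)) {
    with_clean_outputs(out_dir, {
      readr::write_csv(objects, file.path(out_dir, "association.csv"))
      jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      write_manifest(out_dir, "associate", params, list())
    })
  }
  list(objects = objects, nuclei = nuclei, summary = summ)
}

#' Read a run configuration file
#'
#' YAML key-value file mapping directly onto the arguments of the `run_*`
#' functions; unknown algorithm parameters are rejected.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$params)) merge_params(cfg$params)
  cfg
}
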