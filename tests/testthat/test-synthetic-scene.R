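test_that("planted counts per ROI are exactly round(density x area)", {
  # one 1.0 mm^2 square ROI: 1000 x 1000 px at 1 um/px
  sp <- scene_spec(image_height_px = 1100, image_width_px = 1100,
                   pixel_size_um = 1,
                   rois = list(scene_roi(roi_rect("sq", 50, 50, 1000, 1000),
                                         oligomer_density = 10,
                                         plaque_density = 0)),
                   nuclei_density = 40, seed = 3)
  tr <- plan_scene(sp)
  expect_equal(sum(tr$objects$class == "oligomer"), 10)
  expect_equal(sum(tr$objects$class == "plaque"), 0)
  expect_equal(nrow(tr$nuclei), 40)
})

test_that("zero densities plant nuclei only", {
  sp <- scene_spec(rois = list(scene_roi(roi_rect("f", 20, 20, 760, 760),
                                         0, 0)),
                   seed = 5)
  tr <- plan_scene(sp)
  expect_equal(nrow(tr$objects), 0)
  expect_gt(nrow(tr$nuclei), 0)
})

test_that("planning is deterministic for a fixed seed", {
  sp <- small_scene(seed = 12)
  expect_identical(plan_scene(sp), plan_scene(sp))
  sp2 <- small_scene(seed = 13)
  expect_false(identical(plan_scene(sp)$objects, plan_scene(sp2)$objects))
})

test_that("oligomers sit at the perinuclear offset; plaques keep their distance", {
  sp <- small_scene(seed = 21)
  tr <- plan_scene(sp)
  oli <- tr$objects[tr$objects$class == "oligomer", ]
  d_oli <- nearest_nucleus_distance(oli$x_um, oli$y_um,
                                    nucleus_set(tr$nuclei$x_um,
                                                tr$nuclei$y_um))
  expect_true(all(d_oli <= sp$perinuclear_offset_um + 1e-9))
  expect_true(all(d_oli <= sp$perinuclear_offset_um + 0.5 * sp$pixel_size_um))
  pla <- tr$objects[tr$objects$class == "plaque", ]
  d_pla <- nearest_nucleus_distance(pla$x_um, pla$y_um,
                                    nucleus_set(tr$nuclei$x_um,
                                                tr$nuclei$y_um))
  expect_true(all(d_pla >= 3 * sp$nucleus_diameter_um))
})

test_that("planted objects never overlap and stay inside their ROI", {
  sp <- small_scene(seed = 34)
  tr <- plan_scene(sp)
  o <- tr$objects
  n <- nrow(o)
  d <- as.matrix(dist(cbind(o$x_um, o$y_um)))
  lim <- outer(o$semi_major_um, o$semi_major_um, "+")
  expect_true(all(d[upper.tri(d)] > lim[upper.tri(lim)]))
  v_um <- sp$rois[[1]]$roi$vertices * sp$pixel_size_um
  expect_true(all(point_in_polygon(o$x_um, o$y_um, v_um)))
})

test_that("true eccentricity follows the semi-axis closed form", {
  sp <- small_scene(seed = 40, oligomer_density = 0, plaque_density = 80)
  tr <- plan_scene(sp)
  o <- tr$objects
  expect_equal(o$eccentricity,
               sqrt(1 - (o$semi_minor_um / o$semi_major_um)^2))
  expect_equal(o$equivalent_diameter_um,
               2 * sqrt(o$semi_major_um * o$semi_minor_um))
})

test_that("impossible densities fail with an error naming the ROI", {
  sp <- scene_spec(rois = list(scene_roi(roi_rect("tiny", 100, 100, 60, 60),
                                         oligomer_density = 0,
                                         plaque_density = 40000)),
                   seed = 2)
  expect_error(plan_scene(sp, max_attempts = 200), "tiny")
})

test_that("rendering a single disk matches the pixel-membership oracle", {
  truth <- structure(list(
    objects = tibble::tibble(class = "plaque", roi_name = "f",
                             x_um = 50, y_um = 40, semi_major_um = 10,
                             semi_minor_um = 10, orientation_rad = 0,
                             equivalent_diameter_um = 20, eccentricity = 0),
    nuclei = tibble::tibble(roi_name = character(), x_um = double(),
                            y_um = double()),
    seed = 1L), class = "ground_truth")
  sp <- scene_spec(image_height_px = 100, image_width_px = 100,
                   pixel_size_um = 1, rois = list(
                     scene_roi(roi_rect("f", 0, 0, 100, 100), 0, 0)),
                   foreground_intensity = 200, background_intensity = 10,
                   noise_sd = 0, bit_depth = 8, seed = 1)
  img <- render_scene(truth, sp)$deposits
  expect_equal(sum(img == 200L), oracle_disk_count(10))
  expect_equal(sum(img == 10L), 100 * 100 - oracle_disk_count(10))
})

test_that("empty truth renders a constant background", {
  sp <- scene_spec(image_height_px = 50, image_width_px = 60,
                   rois = list(scene_roi(roi_rect("f", 0, 0, 60, 50), 0, 0)),
                   nuclei_density = 0, noise_sd = 0,
                   background_intensity = 10, seed = 1)
  imgs <- render_scene(plan_scene(sp), sp)
  expect_true(all(imgs$deposits == 10L))
  expect_true(all(imgs$nuclei == 10L))
})

test_that("objects extending outside the image are a rendering error", {
  truth <- structure(list(
    objects = tibble::tibble(class = "plaque", roi_name = "f",
                             x_um = 2, y_um = 25, semi_major_um = 10,
                             semi_minor_um = 10, orientation_rad = 0,
                             equivalent_diameter_um = 20, eccentricity = 0),
    nuclei = tibble::tibble(roi_name = character(), x_um = double(),
                            y_um = double()),
    seed = 1L), class = "ground_truth")
  sp <- scene_spec(image_height_px = 50, image_width_px = 50,
                   pixel_size_um = 1,
                   rois = list(scene_roi(roi_rect("f", 0, 0, 50, 50), 0, 0)),
                   noise_sd = 0, seed = 1)
  expect_error(render_scene(truth, sp), "outside")
})

test_that("rendering is bitwise deterministic, and noise respects the seed", {
  sp <- small_scene(seed = 8, noise_sd = 400, side_px = 300L)
  tr <- plan_scene(sp)
  a <- render_scene(tr, sp)
  b <- render_scene(tr, sp)
  expect_identical(unclass(a$deposits)[, ], unclass(b$deposits)[, ])
  expect_identical(unclass(a$nuclei)[, ], unclass(b$nuclei)[, ])
})

test_that("ground truth CSV round-trips losslessly", {
  sp <- small_scene(seed = 16, side_px = 400L)
  tr <- plan_scene(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$objects, tr$objects)
  expect_equal(back$nuclei, tr$nuclei)
  expect_equal(back$seed, tr$seed)
  # row counts: one per object and per nucleus
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(raw), nrow(tr$objects) + nrow(tr$nuclei))
})

test_that("empty truth writes a header-only table", {
  sp <- scene_spec(rois = list(scene_roi(roi_rect("f", 10, 10, 700, 700),
                                         0, 0)),
                   nuclei_density = 0, seed = 4)
  tr <- plan_scene(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(tr, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0)
})
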