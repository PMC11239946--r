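# shared fixture builders

mg <- function(m, ps = 1, bits = 8L, label = "") {
  micrograph(m, pixel_size_um = ps, bit_depth = bits, channel_label = label)
}

# image with one filled disk (pixel-center rule), 0-based center coords
disk_image <- function(nr, nc, cx, cy, r, fg = 200L, bg = 10L, bits = 8L,
                       ps = 1) {
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  m <- matrix(bg, nr, nc)
  m[(x - cx)^2 + (y - cy)^2 <= r^2] <- fg
  mg(m, ps = ps, bits = bits)
}

disk_mask <- function(nr, nc, cx, cy, r) {
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  matrix((x - cx)^2 + (y - cy)^2 <= r^2, nr, nc)
}

# pixel set (0-based x, y) of a rasterized axis-tilted ellipse
ellipse_pixels <- function(cx, cy, a, b, theta = 0) {
  ext <- ceiling(max(a, b)) + 1
  g <- expand.grid(x = floor(cx - ext):ceiling(cx + ext),
                   y = floor(cy - ext):ceiling(cy + ext))
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  g[u^2 + v^2 <= 1, ]
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# clone-screening panel with planted per-replicate signal pixel counts; the
# reference noise fixes the threshold, signal pixels sit safely above it
make_panel <- function(signal_px, n_rep = 3, seed = 101) {
  withr::with_seed(seed, {
    rows <- list()
    for (cl in names(signal_px)) {
      for (r in seq_len(n_rep)) {
        ref <- matrix(pmin(60L, pmax(0L, as.integer(round(
          rnorm(10000, 25, 8))))), 100, 100)
        img <- ref
        k <- signal_px[[cl]]
        if (k > 0) img[seq_len(k)] <- 200L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          clone_id = cl, replicate = r,
          image = list(mg(img)), reference = list(mg(ref)))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# small single-ROI scene used across recovery tests
small_scene <- function(seed, noise_sd = 0, oligomer_density = 150,
                        plaque_density = 40, side_px = 600L, ...) {
  scene_spec(image_height_px = side_px, image_width_px = side_px,
             rois = list(scene_roi(
               roi_rect("field", 20, 20, side_px - 40L, side_px - 40L),
               oligomer_density = oligomer_density,
               plaque_density = plaque_density)),
             noise_sd = noise_sd, seed = seed, ...)
}
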