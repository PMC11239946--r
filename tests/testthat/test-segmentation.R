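test_that("adaptive threshold of a constant image is empty for positive offset", {
  img <- mg(matrix(77L, 30, 30))
  expect_equal(sum(adaptive_threshold(img, 9, offset = 1)), 0)
  expect_equal(sum(adaptive_threshold(img, 9, offset = 0)), 0) # strict >
})

test_that("a bright disk on flat background is fully detected", {
  img <- disk_image(64, 64, 32, 32, 8, fg = 200L, bg = 10L)
  mask <- adaptive_threshold(img, 33, offset = 20)
  expect_true(all(mask[unclass(img) == 200L]))
  # background away from the disk stays empty
  expect_false(any(mask[unclass(img) == 10L & !disk_mask(64, 64, 32, 32, 25)]))
})

test_that("adaptive threshold equals the double-loop local-mean oracle", {
  withr::with_seed(21, {
    m <- matrix(sample.int(256, 64 * 64, replace = TRUE) - 1L, 64, 64)
    got <- adaptive_threshold(mg(m), 9, offset = 5)
    expect_identical(unclass(got)[, ], oracle_adaptive(m, 9, 5))
    # non-square window position handling near borders, small image
    m2 <- matrix(sample.int(256, 20 * 31, replace = TRUE) - 1L, 20, 31)
    got2 <- adaptive_threshold(mg(m2), 7, offset = 3)
    expect_identical(unclass(got2)[, ], oracle_adaptive(m2, 7, 3))
  })
})

test_that("adaptive threshold validates the window", {
  img <- mg(matrix(0L, 20, 20))
  expect_error(adaptive_threshold(img, 8, 5), "odd")
  expect_error(adaptive_threshold(img, 1, 5), "odd|>= 3")
  expect_error(adaptive_threshold(img, 21, 5), "dimension")
})

test_that("foreground count is non-increasing in the offset", {
  withr::with_seed(3, {
    m <- matrix(sample.int(256, 48 * 48, replace = TRUE) - 1L, 48, 48)
    counts <- vapply(c(0, 2, 5, 10, 20, 50),
                     function(o) sum(adaptive_threshold(mg(m), 9, o)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("default offset rescales with bit depth", {
  m8 <- disk_image(60, 60, 30, 30, 6, fg = 200L, bg = 10L, bits = 8L)
  m16 <- disk_image(60, 60, 30, 30, 6, fg = 200L * 257L, bg = 10L * 257L,
                    bits = 16L)
  a8 <- adaptive_threshold(m8, 31)
  a16 <- adaptive_threshold(m16, 31)
  expect_identical(unclass(a8)[, ], unclass(a16)[, ])
})

test_that("opening removes isolated pixels and preserves solid squares up to their corners", {
  m <- matrix(FALSE, 20, 20); m[5, 5] <- TRUE
  expect_equal(sum(morphological_opening(m, 1)), 0)
  # the radius-1 disk is the 5-pixel cross: opening a solid square rounds
  # exactly its four corner pixels and leaves everything else intact
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  want <- sq
  want[cbind(c(6, 6, 25, 25), c(6, 25, 6, 25))] <- FALSE
  expect_identical(unclass(morphological_opening(sq, 1))[, ], want)
})

test_that("opening matches the set-algebra Minkowski oracle", {
  withr::with_seed(8, {
    for (i in 1:6) {
      m <- random_mask(32, 32, p = runif(1, 0.3, 0.7))
      for (r in c(1L, 2L)) {
        expect_identical(unclass(morphological_opening(m, r))[, ],
                         oracle_opening(m, r))
      }
    }
  })
})

test_that("opening is idempotent, anti-extensive, and identity at radius 0", {
  withr::with_seed(13, {
    for (i in 1:5) {
      m <- random_mask(28, 28, 0.55)
      o1 <- morphological_opening(m, 2)
      o2 <- morphological_opening(o1, 2)
      expect_identical(unclass(o2)[, ], unclass(o1)[, ])
      expect_true(all(unclass(o1)[m == FALSE] == FALSE))  # result subset
      expect_identical(unclass(morphological_opening(m, 0))[, ], m)
    }
  })
})

test_that("labeling separates disjoint blobs and handles empty masks", {
  m <- disk_mask(40, 60, 12, 20, 5) | disk_mask(40, 60, 45, 20, 5)
  expect_equal(label_objects(m)$n, 2)
  expect_equal(label_objects(matrix(FALSE, 10, 10))$n, 0)
})

test_that("labeling partitions match the recursive flood-fill oracle", {
  withr::with_seed(99, {
    for (i in 1:50) {
      m <- random_mask(16, 16, runif(1, 0.3, 0.7))
      for (conn in c(4L, 8L)) {
        got <- label_objects(m, conn)
        want <- oracle_label(m, conn)
        expect_equal(got$n, want$n)
        expect_identical(got$labels[, ], want$labels)
      }
    }
  })
})

test_that("4-connectivity yields at least as many components as 8", {
  withr::with_seed(77, {
    for (i in 1:20) {
      m <- random_mask(24, 24, 0.45)
      expect_gte(label_objects(m, 4)$n, label_objects(m, 8)$n)
    }
  })
})

test_that("filter_small removes components below the size floor", {
  m <- matrix(FALSE, 30, 30)
  m[2, 2] <- TRUE                       # size 1
  m[10:11, 10:11] <- TRUE               # size 4
  m[20:24, 20:24] <- TRUE               # size 25
  objs <- label_objects(m)
  expect_equal(filter_small(objs, 1)$n, 3)
  expect_equal(filter_small(objs, 4)$n, 2)
  expect_equal(filter_small(objs, 26)$n, 0)
  f <- filter_small(objs, 4)
  expect_setequal(unique(f$labels[f$labels > 0]), seq_len(f$n))
})

test_that("surviving component count matches an oracle size census", {
  withr::with_seed(31, {
    for (i in 1:10) {
      m <- random_mask(24, 24, 0.5)
      want <- oracle_label(m, 8)
      sizes <- tabulate(want$labels[want$labels > 0], want$n)
      for (thr in c(2L, 4L, 8L)) {
        expect_equal(filter_small(label_objects(m), thr)$n,
                     sum(sizes >= thr))
      }
    }
  })
})

test_that("tissue mask of a constant image is empty", {
  expect_equal(sum(tissue_mask(mg(matrix(40L, 60, 60)), 9, 5, 1)), 0)
})

test_that("noiseless scenes: threshold mask holds every planted pixel, opening keeps every object", {
  sp <- small_scene(seed = 2, noise_sd = 0)
  tr <- plan_scene(sp)
  imgs <- render_scene(tr, sp)
  thr <- adaptive_threshold(imgs$deposits)
  opened <- morphological_opening(thr, 1)
  ps <- sp$pixel_size_um
  for (i in seq_len(nrow(tr$objects))) {
    o <- tr$objects[i, ]
    pix <- ellipse_pixels(o$x_um / ps, o$y_um / ps, o$semi_major_um / ps,
                          o$semi_minor_um / ps, o$orientation_rad)
    idx <- cbind(pix$y + 1, pix$x + 1)
    expect_true(all(thr[idx]))
    # opening may shave boundary pixels of small puncta but never erases
    # or guts an object
    expect_gte(mean(opened[idx]), 0.5)
  }
})

test_that("tissue mask recalls planted pixels under noise", {
  sp <- small_scene(seed = 6, noise_sd = 1000)  # SNR 5
  tr <- plan_scene(sp)
  imgs <- render_scene(tr, sp)
  mask <- tissue_mask(imgs$deposits, offset = 2 * sp$noise_sd)
  ps <- sp$pixel_size_um
  truth_px <- do.call(rbind, lapply(seq_len(nrow(tr$objects)), function(i) {
    o <- tr$objects[i, ]
    ellipse_pixels(o$x_um / ps, o$y_um / ps, o$semi_major_um / ps,
                   o$semi_minor_um / ps, o$orientation_rad)
  }))
  recall <- mean(mask[cbind(truth_px$y + 1, truth_px$x + 1)])
  expect_gte(recall, 0.95)
})
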