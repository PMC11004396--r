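test_that("default spectra satisfy the field's spectral ordering", {
  sp <- default_spectra()
  expect_true(validate_spectra(sp))
  # the orderings the validator encodes, asserted directly
  expect_true(sp$reflectance["seedling", "NIR"] > sp$reflectance["soil", "NIR"])
  expect_true(sp$reflectance["seedling", "RedEdge"] >
                sp$reflectance["soil", "RedEdge"])
  expect_true(sp$reflectance["seedling", "Red"] < sp$reflectance["soil", "Red"])
  expect_true(all(sp$reflectance["tape", ] ==
                    apply(sp$reflectance, 2, min)))
  expect_true(all(sp$dn["tape", ] == apply(sp$dn, 2, min)))
  expect_true(all(sp$reflectance["film", ] == apply(sp$reflectance, 2, max)))
})

test_that("spectral-ordering validator rejects permuted spectra", {
  sp <- default_spectra()
  swapped <- sp
  swapped$reflectance[c("film", "tape"), ] <- sp$reflectance[c("tape", "film"), ]
  swapped$dn[c("film", "tape"), ] <- sp$dn[c("tape", "film"), ]
  expect_error(validate_spectra(swapped), "film")
  no_nir_gain <- sp
  no_nir_gain$reflectance["seedling", c("RedEdge", "NIR")] <-
    sp$reflectance["soil", c("RedEdge", "NIR")] - 0.05
  expect_error(validate_spectra(no_nir_gain), "red-edge and NIR")
})

test_that("scene generation is bit-identical for a fixed configuration", {
  cfg <- scene_config(width_px = 120L, height_px = 120L, rng_seed = 42L)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$scene$visible, b$scene$visible)
  expect_identical(a$scene$reflectance, b$scene$reflectance)
  expect_identical(a$truth$label_map, b$truth$label_map)
  expect_identical(a$truth$seeds, b$truth$seeds)
})

test_that("emergence probability bounds behave as expected", {
  cfg1 <- scene_config(width_px = 150L, height_px = 150L,
                       emergence_prob = 1, grid_px = 50L, rng_seed = 3L)
  full <- generate_scene(cfg1)
  expect_true(all(full$truth$per_grid$rate_pct == 100))
  expect_equal(sum(full$truth$seeds$emerged), nrow(full$truth$seeds))

  cfg0 <- scene_config(width_px = 150L, height_px = 150L,
                       emergence_prob = 0, grid_px = 50L, rng_seed = 3L)
  none <- generate_scene(cfg0)
  expect_equal(sum(none$truth$label_map == 1L), 0L)
  expect_true(all(none$truth$per_grid$ne == 0L))
})

test_that("emerged fraction matches the Bernoulli rate within 3 SE", {
  cfg <- scene_config(width_px = 600L, height_px = 600L,
                      emergence_prob = 0.7, rng_seed = 9L)
  out <- generate_scene(cfg)
  n <- nrow(out$truth$seeds)
  expect_gte(n, 2000L)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(out$truth$seeds$emerged) - 0.7), 3 * se)
  # every emerged seed is painted: the count of seedling components equals
  # the count of emerged seeds (disks cannot merge by construction)
  comp <- count_objects(matrix(as.integer(out$truth$label_map == 1L),
                               nrow(out$truth$label_map)))
  expect_equal(comp$count, sum(out$truth$seeds$emerged))
})

test_that("label map conserves pixels and grid truth is consistent", {
  cfg <- scene_config(width_px = 300L, height_px = 300L, rng_seed = 5L)
  out <- generate_scene(cfg)
  expect_equal(sum(table(out$truth$label_map)), 300L * 300L)
  expect_true(all(out$truth$per_grid$ne <= out$truth$per_grid$ns))
  expect_equal(out$truth$per_grid$rate_pct,
               out$truth$per_grid$ne / out$truth$per_grid$ns * 100)
})

test_that("seedling NDVI exceeds soil NDVI on generated scenes", {
  out <- bundled_scene()
  ndvi <- compute_index(out$scene, "NDVI")$values
  expect_gt(mean(ndvi[out$truth$label_map == 1L], na.rm = TRUE),
            mean(ndvi[out$truth$label_map == 0L], na.rm = TRUE))
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(emergence_prob = 1.2), "emergence_prob")
  expect_error(scene_config(width_px = 0), "width_px")
  expect_error(scene_config(canopy_radius_px_range = c(2, 1)),
               "canopy_radius_px_range")
  # disks of radius 3 at 6-px seed spacing would overlap by construction
  cfg <- scene_config(width_px = 150L, height_px = 150L,
                      canopy_radius_px_range = c(3, 3))
  expect_error(generate_scene(cfg), "overlap")
})

test_that("label sampling draws the requested class counts", {
  out <- bundled_scene()
  lab <- out$labels
  expect_equal(as.integer(table(lab$class)[c("seedling", "soil", "film",
                                             "tape")]),
               c(302L, 224L, 237L, 200L))
  expect_false(any(duplicated(lab[, c("col", "row")])))
  codes <- c(soil = 0L, seedling = 1L, film = 2L, tape = 3L)
  expect_equal(out$truth$label_map[cbind(lab$row, lab$col)],
               unname(codes[lab$class]))
})

test_that("scene and label tables survive a disk round trip", {
  out <- generate_scene(scene_config(width_px = 200L, height_px = 60L,
                                     grid_px = 40L, rng_seed = 8L))
  dir <- withr::local_tempdir()
  write_scene(out$scene, dir, truth = out$truth)
  back <- read_scene(dir)
  expect_equal(dim(back$visible), dim(out$scene$visible))
  # visible DN stored at 8-bit, reflectance at float32 precision
  expect_lt(max(abs(back$visible - out$scene$visible)), 1)
  expect_lt(max(abs(back$reflectance - out$scene$reflectance)), 1e-6)
  lab <- sample_label_pixels(out$truth, counts = c(seedling = 5L, soil = 5L),
                             seed = 1L)
  rownames(lab) <- NULL
  p <- file.path(dir, "labels.csv")
  write_labels(lab, p)
  expect_equal(read_labels(p), lab)
})
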