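test_that("fill closes isolated interior holes", {
  v <- matrix(0L, 5, 5)
  v[2:4, 2:4] <- 1L
  v[3, 3] <- 0L  # hole whose four 4-neighbours are all 1
  out <- morph_filter(as_oriented_mask(v), min_px = 1L)
  expect_equal(out$values[3, 3], 1L)
  expect_true(all(out$values[2:4, 2:4] == 1L))
})

test_that("the area filter deletes exactly the 1-pixel objects", {
  v <- matrix(0L, 9, 9)
  v[2, 2] <- 1L            # isolated single pixel: removed
  v[5, 5:6] <- 1L          # 2-pixel object: kept
  v[8, 8] <- 1L; v[9, 9] <- 1L  # diagonal pair: one 8-connected object, kept
  out <- morph_filter(as_oriented_mask(v))
  expect_equal(out$values[2, 2], 0L)
  expect_true(all(out$values[5, 5:6] == 1L))
  expect_equal(out$values[8, 8] + out$values[9, 9], 2L)
})

test_that("hbreak removes exactly the H-configuration centre pixels", {
  # canonical fixture: vertical bars joined by a one-pixel bridge
  h <- rbind(c(1L, 0L, 1L),
             c(1L, 1L, 1L),
             c(1L, 0L, 1L))
  v <- matrix(0L, 5, 5)
  v[2:4, 2:4] <- h
  out <- morph_filter(as_oriented_mask(v), min_px = 1L)
  expect_equal(out$values[3, 3], 0L)        # bridge removed
  expect_equal(sum(out$values), sum(h) - 1L)

  # the 90-degree rotation (horizontal bars) is also broken
  v2 <- matrix(0L, 5, 5)
  v2[2:4, 2:4] <- t(h)
  out2 <- morph_filter(as_oriented_mask(v2), min_px = 1L)
  expect_equal(out2$values[3, 3], 0L)

  # near-H patterns are left alone: a solid 3x3 block keeps its centre
  v3 <- matrix(0L, 5, 5)
  v3[2:4, 2:4] <- 1L
  out3 <- morph_filter(as_oriented_mask(v3), min_px = 1L)
  expect_equal(out3$values[3, 3], 1L)
})

test_that("diag fills pixels that break background 8-connectivity", {
  # two foreground pixels touching only diagonally: the background crosses
  # the diagonal, so one flanked background pixel per corner is filled
  v <- matrix(0L, 4, 4)
  v[2, 2] <- 1L
  v[3, 3] <- 1L
  out <- morph_filter(as_oriented_mask(v), min_px = 1L)
  expect_equal(out$values[2, 3], 1L)
  expect_equal(out$values[3, 2], 1L)
  # when the diagonal between two flanking foreground pixels is already
  # foreground there is no crossing and nothing is filled
  v2 <- matrix(0L, 4, 4)
  v2[2, 2] <- 1L; v2[2, 3] <- 1L; v2[3, 2] <- 1L  # solid corner
  out2 <- morph_filter(as_oriented_mask(v2), min_px = 1L)
  expect_equal(out2$values[3, 3], 0L)
})

test_that("morphological cleaning never spawns detached components", {
  with_seed_test(31, {
    for (i in 1:10) {
      v <- matrix(rbinom(900, 1, 0.25), 30)
      out <- morph_filter(as_oriented_mask(v), min_px = 1L)
      added <- which(out$values == 1L & v == 0L)
      if (length(added) == 0L) next
      # every added pixel touches the original foreground's 8-neighbourhood
      near <- matrix(0L, 30, 30)
      for (o in list(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),
                     c(1,-1),c(1,0),c(1,1))) {
        sr <- pmin(pmax(row(v) + o[1], 1), 30)
        sc <- pmin(pmax(col(v) + o[2], 1), 30)
        near <- pmax(near, matrix(v[cbind(as.vector(sr), as.vector(sc))], 30))
      }
      expect_true(all(near[added] == 1L), info = paste("iteration", i))
    }
  })
})

test_that("connected components are counted per connectivity", {
  expect_equal(count_objects(matrix(0L, 10, 10))$count, 0L)
  expect_equal(count_objects(blob_mask(1)$values)$count, 1L)
  expect_equal(count_objects(blob_mask(3)$values)$count, 3L)

  diagpair <- matrix(0L, 5, 5)
  diagpair[2, 2] <- 1L
  diagpair[3, 3] <- 1L
  expect_equal(count_objects(diagpair, connectivity = 8)$count, 1L)
  expect_equal(count_objects(diagpair, connectivity = 4)$count, 2L)
  expect_error(label_components(diagpair, connectivity = 6), "connectivity")
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  with_seed_test(17, {
    v <- matrix(rbinom(2500, 1, 0.35), 50)
    mine <- label_components(v, connectivity = 4L)
    ref <- EBImage::bwlabel(v)
    expect_equal(mine$count, max(ref))
    # same partition: label pairs map one-to-one
    expect_equal(length(unique(paste(mine$labels[v == 1],
                                     ref[v == 1]))), mine$count)
  })
})

test_that("centroid assignment partitions components across grid cells", {
  v <- matrix(0L, 288, 288)
  # one 2x2 blob per grid cell corner region + one straddling a boundary
  v[10:11, 10:11] <- 1L
  v[10:11, 200:201] <- 1L
  v[200:201, 10:11] <- 1L
  v[143:146, 50:51] <- 1L  # centroid at row 144.5 -> cell row 2
  m <- as_oriented_mask(v)
  em <- grid_emergence(m, 144L, seeds_sown = 20L)
  expect_equal(nrow(em), 4L)  # 288/144 = 2 x 2 cells
  expect_equal(sum(em$ne), count_objects(v)$count)
  expect_equal(em$ne[em$grid_row == 2 & em$grid_col == 1], 2L)
  expect_equal(em$rate_pct, em$ne / em$ns * 100)
})

test_that("emergence rates follow NE/NS x 100 and guard degenerate NS", {
  v <- matrix(0L, 150, 150)
  m <- as_oriented_mask(v)
  ns_tab <- data.frame(grid_row = 1L, grid_col = 1L, ns = 20L)
  em <- grid_emergence(blob_mask(14, 144, 144, side = 2L, gap = 12L),
                       144L, seeds_sown = ns_tab)
  expect_equal(em$ne, 14L)
  expect_equal(em$rate_pct, 70)
  expect_error(grid_emergence(m, 200L, 20L), "smaller than one grid")
  expect_error(grid_emergence(m, 50L, 0L), "NS > 0")
})

test_that("seeds sown per grid follow the areal seeding rate", {
  expect_equal(seeds_per_grid(1.607, 144L, 26), 139L)
  # a grid of exactly 1 m side at 26 seeds/m^2
  expect_equal(seeds_per_grid(1, 100L, 26), 26L)
  expect_equal(seeds_per_grid(1, 100L, 1e-4), 0L)
  expect_error(grid_emergence(as_oriented_mask(matrix(0L, 100, 100)),
                              100L, seeds_per_grid(1, 100L, 1e-4)),
               "NS > 0")
})

test_that("seedling counts are insensitive to canopy size", {
  base <- list(width_px = 288L, height_px = 288L, rng_seed = 77L)
  small <- generate_scene(do.call(scene_config,
                                  c(base, list(canopy_radius_px_range = c(1, 1)))))
  large <- generate_scene(do.call(scene_config,
                                  c(base, list(canopy_radius_px_range = c(2, 2)))))
  # same emergence draw (radii are drawn after the flags)
  expect_identical(small$truth$seeds$emerged, large$truth$seeds$emerged)
  count_pipeline <- function(out) {
    res <- run_oi_pipeline(out$scene,
                           sample_label_pixels(out$truth, seed = 78L),
                           seeds_sown = out$truth$per_grid[
                             c("grid_row", "grid_col", "ns")])
    sum(res$emergence$ne)
  }
  n_small <- count_pipeline(small)
  n_large <- count_pipeline(large)
  expect_lt(abs(n_small - n_large) / n_small, 0.02)
})
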