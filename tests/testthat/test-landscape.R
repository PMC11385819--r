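test_that("generated landscapes are normalized, reproducible and truncate at zero", {
  sp <- variogram_spec(range_r = 5, trend_t = 0.3, seed = 11)
  g1 <- generate_landscape(sp)
  g2 <- generate_landscape(sp)
  expect_identical(g1$values, g2$values)
  expect_equal(sum(g1$values), 1, tolerance = 1e-9)
  expect_true(all(g1$values >= 0))
  expect_equal(dim(g1$values), c(50L, 50L))
  g3 <- generate_landscape(sp, seed = 12)
  expect_false(identical(g1$values, g3$values))
})

test_that("a deeply negative trend truncates every cell and flags the grid empty", {
  sp <- variogram_spec(range_r = 5, trend_t = -50, seed = 1)
  g <- generate_landscape(sp)
  expect_true(g$empty)
  expect_true(all(g$values == 0))
  expect_error(simulate_movement(g, "F", n_steps = 10),
               "empty landscape")
})

test_that("raw fields reproduce the exponential variogram at lags 1..10", {
  sp <- variogram_spec(range_r = 5, trend_t = 0.3, nrows = 30, ncols = 30)
  fields <- lapply(1:200, function(s) generate_landscape(sp, seed = s)$raw)
  lags <- 1:10
  gamma_hat <- empirical_variogram(fields, lags)
  gamma_theory <- sp$sill * (1 - exp(-lags / sp$range_r))
  # Monte-Carlo tolerance: 10% of the sill
  expect_true(all(abs(gamma_hat - gamma_theory) < 0.1 * sp$sill))
})

test_that("variogram spec rejects invalid parameters", {
  expect_error(variogram_spec(range_r = 0, trend_t = 0))
  expect_error(variogram_spec(range_r = 2, trend_t = 0, sill = 0))
  expect_error(variogram_spec(range_r = 2, trend_t = 0, nugget = -1))
})

test_that("patch delineation handles uniform, empty and checkerboard grids", {
  full <- delineate_patches(matrix(1, 50, 50))
  expect_equal(full$n_patches, 1L)
  expect_equal(full$patches$area, 2500L)

  none <- delineate_patches(matrix(0, 10, 10))
  expect_equal(none$n_patches, 0L)

  cb <- matrix(0, 10, 10)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 1
  expect_equal(delineate_patches(cb, connectivity = 8)$n_patches, 1L)
  expect_equal(delineate_patches(cb, connectivity = 4)$n_patches, sum(cb > 0))
})

test_that("patch labelling matches a flood-fill oracle on random grids", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rbinom(100, 1, 0.45), 10, 10)
    for (conn in c(4, 8)) {
      pm <- delineate_patches(m, connectivity = conn)
      oracle <- flood_fill_label(m, connectivity = conn)
      expect_equal(pm$n_patches, max(oracle))
      # same partition up to relabeling
      if (pm$n_patches > 0) {
        tab <- table(pm$labels[m > 0], oracle[m > 0])
        expect_true(all(rowSums(tab > 0) == 1), info = paste("iter", i, conn))
        expect_true(all(colSums(tab > 0) == 1), info = paste("iter", i, conn))
      }
    }
  }
})

test_that("patch geometry is correct on a hand-built map", {
  m <- matrix(0, 10, 10)
  m[3:4, 3:4] <- 1            # 2x2 patch
  pm <- delineate_patches(m)
  expect_equal(pm$n_patches, 1L)
  expect_equal(pm$patches$area, 4L)
  expect_equal(pm$patches$perimeter, 8L)
  expect_equal(pm$patches$centroid_x, 3.0)   # cols 3:4 -> centers 2.5, 3.5
  expect_equal(pm$patches$centroid_y, 3.0)
  expect_equal(nrow(pm$boundary[[1]]), 4L)   # every cell touches matrix
})

test_that("fragmentation indices match closed forms", {
  # one patch filling the landscape
  fi <- fragmentation_indices(delineate_patches(matrix(1, 12, 12)))
  expect_equal(fi$ai, 100)
  expect_equal(fi$cohesion, 100)
  expect_equal(fi$division, 0)
  expect_equal(fi$proportion, 100)

  # one 2x2 patch in a 10x10 landscape: e = 4, e_max = 4
  m <- matrix(0, 10, 10); m[4:5, 4:5] <- 1
  fi2 <- fragmentation_indices(delineate_patches(m))
  expect_equal(fi2$ai, 100)
  expect_equal(fi2$division, 1 - (4 / 100)^2)
  expect_equal(fi2$proportion, 4)

  # two isolated single cells: e = 0, e_max = 1, cohesion 0
  m3 <- matrix(0, 10, 10); m3[2, 2] <- 1; m3[8, 8] <- 1
  fi3 <- fragmentation_indices(delineate_patches(m3))
  expect_equal(fi3$ai, 0)
  expect_equal(fi3$cohesion, 0)

  # zero patches: AI missing, division 1, proportion 0
  fi0 <- fragmentation_indices(delineate_patches(matrix(0, 5, 5)))
  expect_true(is.na(fi0$ai))
  expect_equal(fi0$division, 1)
  expect_equal(fi0$proportion, 0)
})

test_that("fragmentation indices order the three landscape types", {
  idx <- list()
  for (lev in c("low", "medium", "high")) {
    ai <- coh <- dv <- numeric(0)
    for (s in 1:50) {
      g <- generate_landscape_nonempty(frag_level_spec(lev), seed = 7000 + s)
      fi <- fragmentation_indices(delineate_patches(g))
      ai <- c(ai, fi$ai); coh <- c(coh, fi$cohesion); dv <- c(dv, fi$division)
    }
    idx[[lev]] <- c(ai = mean(ai), cohesion = mean(coh), division = mean(dv))
  }
  expect_gt(idx$low["ai"], idx$medium["ai"])
  expect_gt(idx$medium["ai"], idx$high["ai"])
  expect_gt(idx$low["cohesion"], idx$medium["cohesion"])
  expect_gt(idx$medium["cohesion"], idx$high["cohesion"])
  expect_lt(idx$low["division"], idx$medium["division"])
  expect_lt(idx$medium["division"], idx$high["division"])
})

test_that("ascii grid round-trips through write and read", {
  m <- matrix(0L, 8, 6)
  m[2:3, 2:3] <- 1L
  m[6:7, 4:5] <- 2L
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, metadata = list(seed = 1, level = "test"))
  pm <- read_patch_raster(path)
  expect_equal(pm$n_patches, 2L)
  expect_equal(sort(pm$patches$area), c(4L, 4L))
  expect_true(file.exists(paste0(path, ".meta")))
  # non-integer raster rejected
  path2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(c(0.5, 1, 0, 2), 2, 2), path2)
  expect_error(read_patch_raster(path2), "integer")
  # min_area filter drops small patches
  m2 <- matrix(0L, 8, 6); m2[2:3, 2:3] <- 1L; m2[6, 5] <- 2L
  path3 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m2, path3)
  expect_equal(read_patch_raster(path3, min_area = 2)$n_patches, 1L)
})
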