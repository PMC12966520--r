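# smaller default-like phantom for speed in unit tests
test_cfg <- function(...) {
  noiseless_config(
    grid_shape = c(96, 96, 96),
    aorta_z_range_mm = c(6, 90),
    branch_specs = list(
      list(label = 2L, z0_mm = 16, dir = c(1, 0, 0), length_mm = 36),
      list(label = 2L, z0_mm = 16, dir = c(-1, 0, 0), length_mm = 36),
      list(label = 3L, z0_mm = 60, dir = c(0, 1, 0), length_mm = 36),
      list(label = 4L, z0_mm = 50, dir = c(1, 0, 0), length_mm = 36),
      list(label = 4L, z0_mm = 50, dir = c(-1, 0, 0), length_mm = 36)),
    lesions = list(
      list(center = c(53, 48, 30), radius_mm = 3.0, group = "aorta"),
      list(center = c(64, 48, 16), radius_mm = 2.0, group = "iliac"),
      list(center = c(48, 64, 60), radius_mm = 2.0, group = "mesenteric"),
      list(center = c(34, 48, 50), radius_mm = 1.8, group = "renal")),
    ...)
}

test_that("phantom construction properties", {
  ph <- make_phantom(test_cfg())
  expect_identical(sort(unique(as.vector(ph$arteries$grid))), 0:4)
  # every lesion voxel inside its host vessel group
  for (l in ph$meta$lesions) {
    lab <- c(aorta = 1L, iliac = 2L, mesenteric = 3L, renal = 4L)[[l$group]]
    expect_true(all(ph$arteries$grid[l$voxels] == lab))
    expect_true(all(ph$calc$grid[l$voxels] == 1L))
  }
  # noiseless bands are bimodal with an empty gap
  hu_art <- ph$hu$grid[ph$arteries$grid > 0L & ph$calc$grid == 0L]
  hu_cal <- ph$hu$grid[ph$calc$grid == 1L]
  expect_true(all(hu_art == 300))
  expect_true(all(hu_cal == 900))
  expect_true(all(ph$hu$grid[ph$arteries$grid == 0L] == -50))
})

test_that("phantoms are bit-reproducible under a fixed seed", {
  cfg <- phantom_config(grid_shape = c(64, 64, 64),
                        aorta_z_range_mm = c(4, 60),
                        branch_specs = list(
                          list(label = 2L, z0_mm = 12, dir = c(1, 0, 0),
                               length_mm = 20)),
                        lesions = list(), seed = 77L)
  a <- make_phantom(cfg); b <- make_phantom(cfg)
  expect_identical(a$hu$grid, b$hu$grid)
  expect_identical(a$arteries$grid, b$arteries$grid)
  expect_identical(a$calc$grid, b$calc$grid)
})

test_that("invalid lesions and branches are rejected", {
  bad <- test_cfg()
  bad$lesions <- list(list(center = c(5, 5, 30), radius_mm = 2, group = "aorta"))
  expect_error(make_phantom(bad), "host vessel")
  off <- test_cfg()
  off$branch_specs[[1]]$length_mm <- 500
  expect_error(make_phantom(off), "leaves the grid")
  expect_error(make_high_hu_case(phantom_config(lumen_hu_mean = 300)),
               "exceed 470")
})

test_that("pipeline scores match construction truth on one phantom", {
  ph <- make_phantom(test_cfg())
  truth <- construction_truth(ph)
  sc <- burden_scores(ph$calc, shorten(ph$arteries))
  # calcified volumes agree exactly: lesions sit inside the kept segments
  expect_equal(sc$calc_volume_mm3, truth$calc_volume_mm3)
  expect_equal(sc$cluster_count, truth$cluster_count)
  expect_equal(sc$mean_cluster_size_mm3, truth$mean_cluster_size_mm3)
  # artery volumes agree within a one-voxel surface shell of each segment
  rel <- abs(sc$artery_volume_mm3 - truth$artery_volume_mm3) /
    truth$artery_volume_mm3
  expect_true(all(rel < 0.05))
  expect_equal(sc$burden, truth$burden, tolerance = 0.05)
})

test_that("curved branches are voxelized along the arc", {
  cfg <- noiseless_config(
    grid_shape = c(96, 96, 96), aorta_z_range_mm = c(6, 90),
    branch_specs = list(
      list(label = 4L, z0_mm = 40, dir = c(1, 0, 0), length_mm = 45,
           curvature = 1 / 40)),
    lesions = list())
  ph <- make_phantom(cfg)
  vox <- arrayInd(which(ph$arteries$grid == 4L), dim(ph$arteries$grid))
  # the arc bends superiorly: branch voxels climb in z
  expect_gt(max(vox[, 3]) - 40, 10)
  # straight-line x-extent shorter than the 50 mm arc length
  expect_lt(max(vox[, 1]) - 55, 45)
})

test_that("cohort: truth table sane, configs reproducible", {
  ch <- make_cohort(3, base_cfg = test_cfg(seed = 5L),
                    variability = list(branch_length_range = c(25, 36)))
  expect_length(ch$configs, 3)
  expect_equal(sort(unique(ch$truth$case)), 1:3)
  expect_equal(nrow(ch$truth), 15)          # 3 cases x (4 groups + combined)
  ok <- !is.na(ch$truth$burden)
  expect_true(all(ch$truth$burden[ok] >= 0 & ch$truth$burden[ok] <= 1))
  # regenerating a case from its stored config is bit-identical
  p1 <- make_phantom(ch$configs[[2]])
  p2 <- make_phantom(ch$configs[[2]])
  expect_identical(p1$arteries$grid, p2$arteries$grid)
  expect_identical(p1$calc$grid, p2$calc$grid)
  # lesion-free cohort -> all truth burdens zero
  base0 <- test_cfg(seed = 9L)
  ch0 <- make_cohort(2, base_cfg = base0,
                     variability = list(branch_length_range = c(25, 36),
                                        lesion_rate = c(aorta = 0, iliac = 0,
                                                        mesenteric = 0,
                                                        renal = 0)))
  expect_true(all(ch0$truth$burden[!is.na(ch0$truth$burden)] == 0))
})

test_that("high-lumen case reproduces the fixed-threshold failure", {
  ph <- make_high_hu_case(test_cfg(lumen_hu_mean = 550))
  roi <- ph$arteries$grid > 0L
  fixed <- apply_threshold(ph$hu, roi, 470)
  expect_gte(sum(fixed$grid == 1L) / sum(roi), 0.99)
  res <- optimal_threshold(ph$hu, roi, ph$calc)
  expect_gte(res$best_dice, 0.95)
  # control at lumen 300: the fixed threshold works
  ctrl <- make_phantom(test_cfg())
  fixed_ctrl <- apply_threshold(ctrl$hu, ctrl$arteries$grid > 0L, 470)
  expect_equal(fixed_ctrl$grid, ctrl$calc$grid)
})
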