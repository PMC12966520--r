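cfg_default <- shortening_config()

test_that("config invariants are enforced", {
  expect_equal(cfg_default$n_dilations, 25L)
  expect_equal(cfg_default$aorta_dilations_for_stump, 2L)
  expect_error(shortening_config(connectivity = 4), "connectivity")
  expect_error(shortening_config(target_length_mm = -1))
})

test_that("find_side_components matches a flood-fill oracle", {
  tree <- small_tree()
  comps <- find_side_components(tree, cfg_default)
  expect_length(comps, 3)
  expect_equal(sort(vapply(comps, `[[`, 1L, "label")), c(2L, 3L, 4L))
  for (cmp in comps) {
    m <- tree$grid == cmp$label
    lab <- ora_components(m, 6)
    expect_equal(sort(cmp$voxels), sort(which(lab == lab[cmp$voxels[1]])))
  }
  # map with only aorta -> empty list
  only_a <- artery_label_map(array(1L, c(4, 4, 4)))
  expect_length(find_side_components(only_a, cfg_default), 0)
})

test_that("a 1-voxel gap splits a component in two", {
  d <- c(40, 20, 20)
  g <- array(0L, d)
  g[5:15, 9:11, 9:11] <- 4L
  g[17:30, 9:11, 9:11] <- 4L            # gap at x = 16
  g[1:4, 1:20, 1:20] <- 1L
  comps <- find_side_components(artery_label_map(g), cfg_default)
  expect_length(comps, 2)
  expect_true(all(vapply(comps, `[[`, 1L, "label") == 4L))
})

test_that("define_stump: collar, detachment, islet rule", {
  d <- c(60, 24, 24)
  aorta <- array(FALSE, d); aorta[1:10, , ] <- TRUE
  # straight branch abutting the aorta: stump = <=2-voxel collar
  comp <- array(FALSE, d); comp[11:50, 10:14, 10:14] <- TRUE
  st <- define_stump(comp, aorta, cfg_default)
  expect_identical(array(st, d), comp & ora_dilate(ora_dilate(aorta, 6), 6))
  expect_true(all(arrayInd(which(st), d)[, 1] <= 12))

  # branch 30 mm away everywhere -> empty stump, detached outcome
  far <- array(FALSE, d); far[41:55, 10:14, 10:14] <- TRUE
  st2 <- define_stump(far, aorta, cfg_default)
  expect_false(any(st2))
  expect_true(isTRUE(attr(st2, "detached")))
})

test_that("stump islets: retained at 2.0 cm, discarded at 3.0 cm", {
  for (gap in c(20L, 30L)) {
    d <- c(60, 50, 60)
    aorta <- array(FALSE, d); aorta[1:10, , ] <- TRUE
    # U-shaped component touching the aorta at z=10 and z=10+gap
    comp <- tube_mask(d, c(11, 25, 10), c(40, 25, 10)) |
      tube_mask(d, c(40, 25, 10), c(40, 25, 10 + gap)) |
      tube_mask(d, c(40, 25, 10 + gap), c(11, 25, 10 + gap))
    st <- define_stump(comp, aorta, cfg_default)
    sub <- ora_components(array(st, d), 6)
    if (gap == 20L) {
      expect_equal(max(sub), 2)         # secondary islet retained and merged
      expect_equal(attr(st, "removed_islets"), 0L)
    } else {
      expect_equal(max(sub), 1)         # beyond 2.5 cm: background
      expect_equal(attr(st, "removed_islets"), 1L)
    }
  }
})

test_that("grow_stump is geodesic and equals the BFS oracle", {
  d <- c(60, 24, 24)
  aorta <- array(FALSE, d); aorta[1:10, , ] <- TRUE
  comp <- array(FALSE, d); comp[11:55, 10:14, 10:14] <- TRUE
  st <- define_stump(comp, aorta, cfg_default)
  gr <- grow_stump(st, comp, cfg_default)
  # extends exactly n_dilations voxels beyond the most distal stump voxel
  expect_equal(max(arrayInd(which(gr), d)[, 1]),
               max(arrayInd(which(st), d)[, 1]) + cfg_default$n_dilations)
  # oracle equivalence
  dist <- ora_geodesic(comp, array(st, d), 6)
  expect_identical(gr, array(dist <= cfg_default$n_dilations, d))

  # short tube saturates: entire component retained
  shortc <- array(FALSE, d); shortc[11:20, 10:14, 10:14] <- TRUE
  st2 <- define_stump(shortc, aorta, cfg_default)
  expect_identical(grow_stump(st2, shortc, cfg_default), shortc)

  # empty stump -> empty output
  expect_false(any(grow_stump(array(FALSE, d), comp, cfg_default)))
})

test_that("growth follows arc length, not Euclidean distance", {
  # U-shaped tube: geodesic ~40 steps end to end, Euclidean gap 4 voxels
  d <- c(40, 20, 20)
  comp <- tube_mask(d, c(5, 8, 10), c(23, 8, 10)) |
    tube_mask(d, c(23, 8, 10), c(23, 12, 10)) |
    tube_mask(d, c(23, 12, 10), c(5, 12, 10))
  seed <- array(FALSE, d); seed[5, 8, 10] <- TRUE
  gr <- grow_stump(seed, comp, cfg_default)       # 25 steps
  expect_false(gr[5, 12, 10])   # Euclidean distance 4, geodesic 40
  dist <- ora_geodesic(comp, seed, 6)
  expect_identical(gr, array(dist <= 25, d))
})

test_that("growth is monotone in n_dilations", {
  d <- c(40, 16, 16)
  comp <- tube_mask(d, c(5, 8, 8), c(38, 8, 8), half = 1)
  seed <- array(FALSE, d); seed[5:6, 7:9, 7:9] <- comp[5:6, 7:9, 7:9]
  prev <- NULL
  for (n in c(5L, 10L, 15L, 20L)) {
    g <- grow_stump(seed, comp, shortening_config(n_dilations = n))
    if (!is.null(prev)) expect_true(all(g[prev]))
    prev <- g
  }
})

test_that("truncate_aorta cuts 1 cm above the highest side artery", {
  d <- c(20, 20, 101)
  aorta <- array(FALSE, d); aorta[8:12, 8:12, 1:101] <- TRUE
  sides <- array(FALSE, d); sides[14, 10, 60] <- TRUE
  out <- truncate_aorta(aorta, sides, cfg_default)
  expect_equal(max(arrayInd(which(out), d)[, 3]), 70)
  expect_identical(out[, , 1:70], aorta[, , 1:70])   # nothing below altered

  # highest side artery already at the aortic top -> unchanged
  top <- array(FALSE, d); top[14, 10, 101] <- TRUE
  expect_identical(truncate_aorta(aorta, top, cfg_default), aorta)

  # two branches: the global maximum governs the cut
  two <- array(FALSE, d); two[14, 10, 60] <- TRUE; two[2, 10, 80] <- TRUE
  out2 <- truncate_aorta(aorta, two, cfg_default)
  expect_equal(max(arrayInd(which(out2), d)[, 3]), 90)

  expect_error(truncate_aorta(aorta, array(FALSE, d), cfg_default),
               "no side-artery")
  expect_warning(
    out3 <- truncate_aorta(aorta, array(FALSE, d), cfg_default,
                           on_empty = "pass"),
    "unchanged")
  expect_identical(out3, aorta)
})

test_that("shorten: subsets, label conservation, idempotence, determinism", {
  tree <- small_tree()
  s1 <- shorten(tree, cfg_default)
  # output side voxels are subsets of input voxels of the same label
  for (lab in 2:4)
    expect_true(all(tree$grid[s1$grid == lab] == lab))
  expect_true(all(unique(as.vector(s1$grid)) %in% unique(as.vector(tree$grid))))
  # idempotence, voxel for voxel
  s2 <- shorten(s1, cfg_default)
  expect_identical(s2$grid, s1$grid)
  # determinism
  expect_identical(shorten(tree, cfg_default)$grid, s1$grid)
  # provenance log
  log <- attr(s1, "shortening")
  expect_length(log$components, 3)
  expect_false(any(vapply(log$components, `[[`, TRUE, "detached")))
})

test_that("shorten drops detached components and validates input", {
  d <- c(48, 24, 24)
  g <- array(0L, d)
  g[1:8, , ] <- 1L
  g[9:40, 10:14, 10:14] <- 4L
  g[44:47, 10:14, 10:14] <- 2L          # island far from the aorta
  s <- shorten(artery_label_map(g), cfg_default)
  expect_false(any(s$grid == 2L))
  log <- attr(s, "shortening")$components
  expect_true(any(vapply(log, `[[`, TRUE, "detached")))

  expect_error(shorten(artery_label_map(array(0L, c(4, 4, 4)))), "aorta")
  g2 <- array(0L, c(4, 4, 4)); g2[1, 1, 1] <- 2L
  expect_error(shorten(artery_label_map(g2)), "aorta")
})
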