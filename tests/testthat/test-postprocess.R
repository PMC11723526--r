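test_that("markers: one label per centroid component, background outside", {
  nuc <- disk_mask(24, 24, 12, 12, 6)
  cen <- matrix(0L, 24, 24); cen[12, 12] <- 1L
  mk <- build_markers(nuc, cen)
  expect_equal(mk$K, 1)
  expect_equal(sort(unique(c(mk$labels))), c(0L, 1L, 2L))
  expect_true(all(mk$labels[nuc == 1 & cen == 0] == 0))  # nucleus body unknown

  # two touching disks, two dots
  nuc2 <- pmax(disk_mask(30, 44, 15, 14, 9), disk_mask(30, 44, 15, 28, 9))
  cen2 <- matrix(0L, 30, 44); cen2[15, 14] <- 1L; cen2[15, 28] <- 1L
  mk2 <- build_markers(nuc2, cen2)
  expect_equal(mk2$K, 2)
  expect_true(all(table(mk2$labels[mk2$labels >= 2]) == 1))  # disjoint dots

  # a dot outside the nuclei mask is dropped with a warning
  cen3 <- cen2; cen3[2, 2] <- 1L
  expect_warning(mk3 <- build_markers(nuc2, cen3), "outside")
  expect_equal(mk3$K, 2)

  # no centroids at all: only the background marker remains
  mk4 <- build_markers(nuc, matrix(0L, 24, 24))
  expect_equal(mk4$K, 0)
})

test_that("watershed labels a single nucleus without any watershed line", {
  nuc <- disk_mask(24, 24, 12, 12, 7)
  cen <- matrix(0L, 24, 24); cen[12, 12] <- 1L
  lm <- watershed_segment(build_markers(nuc, cen), nuc)
  expect_equal(lm$n, 1)
  expect_true(all(lm$labels[nuc == 1] == 1L))
  expect_equal(sum(lm$labels == -1L), 0)
})

test_that("watershed separates two overlapping disks along the overlap lens", {
  H <- 30; W <- 40
  nuc <- pmax(disk_mask(H, W, 15, 14, 10), disk_mask(H, W, 15, 28, 10))
  cen <- matrix(0L, H, W); cen[15, 14] <- 1L; cen[15, 28] <- 1L
  lm <- watershed_segment(build_markers(nuc, cen), nuc)
  expect_equal(length(setdiff(unique(c(lm$labels)), c(0L, -1L))), 2)
  wl <- which(lm$labels == -1L, arr.ind = TRUE)
  expect_gt(nrow(wl), 0)
  # the line lies in the overlap lens (between the two centres)
  expect_true(all(wl[, 2] >= 18 & wl[, 2] <= 24))
  # no label-1 pixel 4-adjacent to a label-2 pixel without a line between
  lab <- lm$labels
  for (d in list(c(1, 0), c(0, 1))) {
    a <- lab[1:(H - d[1]), 1:(W - d[2])]
    b <- lab[(1 + d[1]):H, (1 + d[2]):W]
    expect_false(any(a > 0 & b > 0 & a != b))
  }
})

test_that("watershed with empty centroids yields zero instances", {
  nuc <- disk_mask(20, 20, 10, 10, 6)
  lm <- watershed_segment(build_markers(nuc, matrix(0L, 20, 20)), nuc)
  expect_equal(lm$n, 0)
  expect_equal(sum(lm$labels > 0), 0)
})

test_that("flooding agrees exactly with the naive priority-flood oracle", {
  for (seed in 1:6) {
    sc <- random_nuclei_scene(seed)
    mk <- build_markers(sc$nuclei, sc$centroid)
    relief <- -distance_transform(sc$nuclei)
    fast <- myoseg:::.watershed_flood(mk$labels, relief)
    slow <- ws_oracle(mk$labels, relief)
    expect_identical(fast, slow, label = sprintf("seed %d", seed))
  }
})

test_that("adding a marker never decreases the instance count", {
  for (seed in c(3, 9)) {
    sc <- random_nuclei_scene(seed, n = 6)
    cen_idx <- which(sc$centroid == 1L, arr.ind = TRUE)
    drop1 <- sc$centroid
    drop1[cen_idx[1, 1], cen_idx[1, 2]] <- 0L
    n_full <- watershed_segment(build_markers(sc$nuclei, sc$centroid),
                                sc$nuclei)
    n_less <- watershed_segment(build_markers(sc$nuclei, drop1), sc$nuclei)
    count_inst <- function(lm) length(setdiff(unique(c(lm$labels)), c(0L, -1L)))
    expect_gte(count_inst(n_full), count_inst(n_less))
  }
})

test_that("skeletonization: degenerate inputs, bar core, idempotence, containment", {
  expect_equal(sum(skeletonize(matrix(0L, 10, 10))), 0)
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  expect_identical(skeletonize(one), one)

  bar <- matrix(0L, 9, 37); bar[4:6, 4:34] <- 1L   # 3 x 31 bar
  sk <- skeletonize(bar)
  px <- which(sk == 1L, arr.ind = TRUE)
  expect_true(all(px[, 1] == 5))                    # middle row only
  # two-subiteration thinning eats up to ~1.5 px per end of the bar
  expect_gte(nrow(px), 28); expect_lte(nrow(px), 31)
  # the path is a contiguous run of columns
  expect_equal(sort(px[, 2]), seq(min(px[, 2]), max(px[, 2])))

  for (seed in 1:5) {
    sc <- generate_scene(scene_spec(seed = seed, n_nuclei = 0))
    sk <- skeletonize(sc$truth$myotube_mask)
    expect_identical(skeletonize(sk), sk)                  # idempotent
    expect_true(all(sc$truth$myotube_mask[sk == 1L] == 1L)) # contained
    # thinning preserves the component count (topology)
    expect_equal(flood_count(sk, 8), flood_count(sc$truth$myotube_mask, 8))
  }
})

test_that("branch decomposition: line, Y-shape, ring", {
  line <- matrix(0L, 9, 20); line[5, 3:18] <- 1L
  br <- extract_branches(line)
  expect_length(br$branches, 1)
  expect_equal(nrow(br$junctions), 0)
  expect_equal(nrow(br$endpoints), 2)
  expect_equal(nrow(br$branches[[1]]), 16)

  # Y: three 15-px arms meeting at one pixel
  y <- matrix(0L, 41, 41)
  for (i in 1:15) {
    y[20 - i + 1, 20] <- 1L        # up
    y[20 + i, 20 - i] <- 1L        # down-left diagonal
    y[20 + i, 20 + i] <- 1L        # down-right diagonal
  }
  y[20, 20] <- 1L
  bry <- extract_branches(y)
  expect_length(bry$branches, 3)
  expect_equal(nrow(bry$junctions), 1)
  expect_equal(bry$junctions[1, ], c(row = 20L, col = 20L),
               ignore_attr = TRUE)
  expect_equal(nrow(bry$endpoints), 3)
  # each branch includes the shared junction pixel
  for (b in bry$branches)
    expect_true(any(b[, 1] == 20 & b[, 2] == 20))

  # ring: one cyclic branch, no endpoints (diamond ring: every pixel has
  # exactly two 8-neighbours; a rectangle would add corner diagonals)
  ring <- matrix(0L, 21, 21)
  for (r in 1:21) for (c in 1:21)
    if (abs(r - 11) + abs(c - 11) == 6) ring[r, c] <- 1L
  brr <- extract_branches(ring)
  expect_length(brr$branches, 1)
  expect_equal(nrow(brr$junctions), 0)
  expect_equal(nrow(brr$endpoints), 0)
  expect_equal(nrow(brr$branches[[1]]), sum(ring))
})

test_that("diameter: rendered strokes, pixel-row bars, unit scaling, disks", {
  # generator stroke (continuous band, arbitrary orientation): within 1 px
  sc <- generate_scene(scene_spec(n_tubes = 1, tube_width_range = c(11L, 11L),
                                  tube_curvature = 0, branch_prob = 0,
                                  n_nuclei = 0, seed = 77))
  mask <- sc$truth$myotube_mask
  br <- extract_branches(skeletonize(mask))$branches[[1]]
  dm <- measure_diameter(mask, br)
  expect_lt(abs(dm$mean_um - 11), 1)
  dm_half <- measure_diameter(mask, br, um_per_px = 0.5)
  expect_equal(dm_half$mean_um, dm$mean_um / 2)

  # axis-aligned bar of w whole pixel rows: reads w + 1 exactly (background
  # pixel centres sit half a pixel beyond the ink on each side)
  bar <- straight_tube_mask(40, 60, 11)
  brb <- extract_branches(skeletonize(bar))$branches[[1]]
  expect_equal(measure_diameter(bar, brb)$mean_um, 12)

  disk <- disk_mask(41, 41, 21, 21, 10)
  ctr <- matrix(c(21L, 21L), 1)
  dd <- measure_diameter(disk, ctr)
  expect_lt(abs(dd$mean_um - 20), 2)             # ~2r at the centre

  expect_error(measure_diameter(bar * 0L, brb), "lie on the myotube mask")
  short <- measure_diameter(bar, brb[1:3, , drop = FALSE])
  expect_true(short$flagged)
})

test_that("length: unit steps, diagonals, mixed paths, order checking", {
  horiz <- cbind(5L, 1:10)
  expect_equal(measure_length(horiz), 9)
  diag <- cbind(1:10, 1:10)
  expect_equal(measure_length(diag), 9 * sqrt(2))
  lshape <- rbind(cbind(1L, 1:6), cbind(2:6, 6L))  # 5 right + 5 down, 11 px
  expect_equal(measure_length(lshape), 10)
  expect_equal(measure_length(lshape, um_per_px = 2), 20)
  shuffled <- diag[c(1, 5, 2, 9, 3), ]
  expect_error(measure_length(shuffled), "ordered")
  expect_equal(measure_length(diag[1, , drop = FALSE]), 0)
})

test_that("count_nuclei honours an ROI through the centroid rule", {
  lm <- matrix(0L, 20, 30)
  lm[3:6, 3:6] <- 1L; lm[10:14, 10:14] <- 2L; lm[3:6, 22:26] <- 3L
  expect_equal(count_nuclei(lm), 3)
  roi <- matrix(0L, 20, 30); roi[1:16, 1:16] <- 1L
  expect_equal(count_nuclei(lm, roi), 2)
  expect_equal(count_nuclei(lm, roi * 0L), 0)
})

test_that("nucleus counting from perfect inputs is exact up to overlap 0.4", {
  for (ov in c(0, 0.2, 0.4)) {
    sc <- generate_scene(scene_spec(n_nuclei = 10, overlap_fraction = ov,
                                    n_tubes = 0, seed = 21))
    lm <- watershed_segment(
      build_markers(sc$truth$nuclei_mask, sc$truth$centroid_mask),
      sc$truth$nuclei_mask)
    expect_equal(count_nuclei(lm), 10, label = sprintf("overlap %.1f", ov))
  }
})

test_that("quantify_image closes the loop on synthetic scenes", {
  # straight single tube of known width; nuclei scattered
  sc <- generate_scene(scene_spec(n_tubes = 1, tube_width_range = c(11L, 11L),
                                  tube_curvature = 0, branch_prob = 0,
                                  n_nuclei = 8, overlap_fraction = 0,
                                  seed = 13))
  q <- quantify_image(list(p_myotube = sc$truth$myotube_mask,
                           p_nuclei = sc$truth$nuclei_mask,
                           p_centroid = sc$truth$centroid_mask))
  expect_equal(nrow(q$myotubes), 1)
  expect_lt(abs(q$myotubes$diameter_um - 11), 1)
  expect_equal(count_nuclei(q$nuclei), 8)
  # nuclei inside the tube = ground-truth point-in-mask count
  cen_idx <- which(sc$truth$centroid_mask == 1L, arr.ind = TRUE)
  expect_equal(q$myotubes$n_nuclei, sum(sc$truth$myotube_mask[cen_idx]))

  # empty predictions: empty records
  empty <- quantify_image(list(p_myotube = matrix(0, 64, 64),
                               p_nuclei = matrix(0, 64, 64),
                               p_centroid = matrix(0, 64, 64)))
  expect_equal(nrow(empty$branches), 0)
  expect_equal(nrow(empty$myotubes), 0)

  # two disjoint tubes -> two myotube ids
  two <- pmax(straight_tube_mask(64, 64, 7, row = 16),
              straight_tube_mask(64, 64, 7, row = 48))
  q2 <- quantify_image(list(p_myotube = two, p_nuclei = two * 0,
                            p_centroid = two * 0))
  expect_equal(nrow(q2$myotubes), 2)
  expect_equal(sort(q2$myotubes$myotube_id), c(1, 2))
})

test_that("watershed conservation: every foreground pixel ends labelled or on a line", {
  for (seed in c(4, 17)) {
    sc <- random_nuclei_scene(seed)
    mk <- build_markers(sc$nuclei, sc$centroid)
    lm <- watershed_segment(mk, sc$nuclei)
    # nucleus pixels are never left unassigned: instance label or line
    expect_true(all(lm$labels[sc$nuclei == 1L] != 0L))
    # and nothing outside the unknown region was ever relabelled
    expect_true(all(lm$labels[mk$labels == 1L] == 0L))
  }
})
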