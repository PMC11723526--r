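test_that("confusion counts match cell-by-cell enumeration", {
  pred <- matrix(0L, 4, 4); pred[1:2, 1:2] <- 1L
  truth <- matrix(0L, 4, 4); truth[2:3, 2:3] <- 1L
  cc <- confusion(pred, truth)
  expect_equal(cc$TP, 1); expect_equal(cc$FP, 3)
  expect_equal(cc$FN, 3); expect_equal(cc$TN, 9)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 16)

  same <- confusion(truth, truth)
  expect_equal(same$FP, 0); expect_equal(same$FN, 0)
  inv <- confusion(1L - truth, truth)
  expect_equal(inv$TP, 0); expect_equal(inv$TN, 0)
  expect_error(confusion(pred * 2L, truth), "binary")
})

test_that("iou and dice match their formulas and conventions", {
  pred <- matrix(0L, 4, 4); pred[1:2, 1:2] <- 1L
  truth <- matrix(0L, 4, 4); truth[2:3, 2:3] <- 1L
  cc <- confusion(pred, truth)
  expect_equal(iou(cc), 1 / 7)
  expect_equal(dice(cc), 0.25)
  expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)))

  expect_equal(iou(truth, truth), 1)
  expect_equal(dice(truth, truth), 1)
  a <- matrix(0L, 3, 3); a[1, 1] <- 1L
  b <- matrix(0L, 3, 3); b[3, 3] <- 1L
  expect_equal(iou(a, b), 0)
  expect_equal(dice(a, b), 0)
  z <- matrix(0L, 3, 3)
  expect_message(v <- iou(z, z), "empty")
  expect_equal(v, 1)
  suppressMessages(expect_equal(dice(z, z), 1))
  expect_equal(iou(z, a), 0)
})

test_that("Dice = 2 IoU / (1 + IoU) and both metrics are symmetric", {
  set.seed(44)
  for (i in 1:100) {
    a <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10)
    b <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10)
    i1 <- iou(a, b); d1 <- dice(a, b)
    expect_equal(d1, 2 * i1 / (1 + i1), tolerance = 1e-12)
    expect_equal(i1, iou(b, a))
    expect_equal(d1, dice(b, a))
    expect_true(i1 >= 0 && i1 <= 1 && d1 >= i1)
  }
})

test_that("otsu and yen equal an exhaustive 256-bin objective sweep", {
  set.seed(7)
  for (i in 1:5) {
    # random 8-bit image with a rough two-population structure
    v <- c(rbinom(300, 255, runif(1, .1, .4)), rbinom(200, 255, runif(1, .6, .9)))
    x <- matrix(v / 255, 25, 20)
    h <- tabulate(pmin(floor(pmax(x, 0) * 256) + 1, 256), 256)
    centers <- (1:256 - 0.5) / 256
    # otsu oracle: maximize between-class variance over every split
    bcv <- sapply(1:255, function(k) {
      w0 <- sum(h[1:k]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) return(-Inf)
      m0 <- sum(h[1:k] * centers[1:k]) / w0
      m1 <- sum(h[(k + 1):256] * centers[(k + 1):256]) / w1
      w0 * w1 * (m0 - m1)^2
    })
    expect_equal(threshold_value(x, "otsu"), which.max(bcv) / 256)
    # yen oracle: maximize the Yen entropic correlation criterion
    p <- h / sum(h)
    yc <- sapply(1:255, function(k) {
      P0 <- sum(p[1:k]); G0 <- sum(p[1:k]^2); G1 <- sum(p[(k + 1):256]^2)
      if (P0 <= 0 || P0 >= 1 || G0 <= 0 || G1 <= 0) return(-Inf)
      -log(G0 * G1) + 2 * log(P0 * (1 - P0))
    })
    expect_equal(threshold_value(x, "yen"), which.max(yc) / 256)
  }
})

test_that("isodata and li thresholds satisfy their fixed-point definitions", {
  set.seed(8)
  v <- c(rnorm(400, 0.25, 0.06), rnorm(300, 0.75, 0.08))
  x <- matrix(pmin(pmax(v, 0), 1), 70, 10)
  t_iso <- threshold_value(x, "isodata")
  centers <- (1:256 - 0.5) / 256
  h <- tabulate(pmin(floor(x * 256) + 1, 256), 256)
  m0 <- sum(h[centers <= t_iso] * centers[centers <= t_iso]) /
    sum(h[centers <= t_iso])
  m1 <- sum(h[centers > t_iso] * centers[centers > t_iso]) /
    sum(h[centers > t_iso])
  expect_lt(abs(t_iso - (m0 + m1) / 2), 1 / 256)

  t_li <- threshold_value(x, "li")
  g <- centers + 1 / 512
  tl <- t_li + 1 / 512
  mb <- sum(h[g <= tl] * g[g <= tl]) / sum(h[g <= tl])
  mf <- sum(h[g > tl] * g[g > tl]) / sum(h[g > tl])
  expect_lt(abs(tl - (mb - mf) / (log(mb) - log(mf))), 1 / 256)
  # both separate the two modes
  expect_true(t_iso > 0.3 && t_iso < 0.7)
  expect_true(t_li > 0.2 && t_li < 0.7)
})

test_that("mean and minimum thresholds behave per definition", {
  x <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(threshold_value(x, "mean"), 0.5)
  expect_equal(threshold_segment(x, "mean"), matrix(c(0L, 0L, 1L, 1L), 2))

  set.seed(9)
  v <- c(rnorm(2000, 0.2, 0.05), rnorm(1000, 0.8, 0.05))
  x2 <- matrix(pmin(pmax(v, 0), 1), 100, 30)
  t_min <- threshold_value(x2, "minimum")
  expect_true(t_min > 0.35 && t_min < 0.65)   # valley between the modes
})

test_that("all six methods recover a clean two-level segmentation", {
  set.seed(10)
  truth <- matrix(rbinom(900, 1, 0.5), 30)    # balanced foreground
  x <- ifelse(truth == 1, 0.9, 0.1)
  for (m in c("isodata", "li", "mean", "minimum", "otsu", "yen")) {
    expect_identical(threshold_segment(x, m), matrix(as.integer(truth), 30),
                     label = m)
  }
  expect_warning(t0 <- threshold_value(matrix(0.4, 5, 5), "otsu"), "constant")
  expect_equal(sum(matrix(0.4, 5, 5) > t0), 0)
})

test_that("cross-validation folds partition images reproducibly", {
  f <- crossval_folds(40, k = 5, seed = 3)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 8))
  expect_setequal(unlist(f), 1:40)
  expect_identical(f, crossval_folds(40, k = 5, seed = 3))
  expect_false(identical(f, crossval_folds(40, k = 5, seed = 4)))
  expect_error(crossval_folds(40, k = 1), "k >= 2")
  expect_error(crossval_folds(3, k = 5), "at least")
})

test_that("method comparison reports the Table-2 layout and a truth ceiling", {
  scenes <- lapply(1:3, function(s) {
    sc <- generate_scene(scene_spec(seed = s + 50))
    list(image = sc$image, truth = sc$truth)
  })
  rep <- compare_methods(scenes,
                         segmenter = function(img) {
                           # ground truth as the segmenter: the ceiling column
                           scenes[[which(sapply(scenes, function(s)
                             identical(s$image$pixels, img$pixels)))]]$truth$myotube_mask
                         })
  expect_equal(nrow(rep), 7)
  expect_equal(rep$method[1], "learned")
  expect_equal(rep$iou[1], 1)
  expect_equal(rep$dice[1], 1)
  # gradient + noise scenes: every threshold scores strictly below the ceiling
  expect_true(all(rep$iou[-1] < rep$iou[1]))
  # noise holes and ragged boundaries inflate spurious skeleton branches
  # for the thresholds relative to the clean masks
  expect_gt(rep$mean_branches[rep$method == "otsu"],
            rep$mean_branches[rep$method == "learned"])
})
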