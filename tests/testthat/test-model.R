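# a small config keeps these structural tests fast; the full-width
# architecture is exercised once in the acceptance suite
small_cfg <- function(n_residual_blocks = 2L, ...)
  model_config(base_channels = 4L, n_residual_blocks = n_residual_blocks,
               seed = 7L, ...)

test_that("encoder-decoder shapes: halve twice, restore, one map per head", {
  m <- build_model(small_cfg())
  out <- forward(m, array(runif(2 * 64 * 64), c(2, 64, 64)))
  sh <- attr(out, "shapes")
  expect_equal(sh$down1, c(4L, 32L, 32L))      # channels x H/2 x W/2
  expect_equal(sh$down2, c(8L, 16L, 16L))
  expect_equal(sh$residual, c(16L, 16L, 16L))  # doubled by the 1x1 projection
  expect_equal(sh$up1, c(8L, 32L, 32L))
  expect_equal(sh$head, c(1L, 64L, 64L))
  for (p in out) {
    expect_equal(dim(p), c(64L, 64L))
    expect_true(all(p > 0 & p < 1))            # sigmoid range
  }
  # fully convolutional: a different size divisible by 4 works unchanged
  out2 <- forward(m, array(runif(2 * 32 * 48), c(2, 32, 48)))
  expect_equal(dim(out2$p_centroid), c(32L, 48L))
  expect_error(forward(m, array(0, c(2, 30, 30))), "divisible by 4")
})

test_that("strict_128 variant keeps 2*base channels through the residuals", {
  m <- build_model(small_cfg(strict_128 = TRUE))
  out <- forward(m, array(0, c(2, 32, 32)))
  # 2*base = 8 channels (no 1x1 projection) at the quarter-resolution grid
  expect_equal(attr(out, "shapes")$residual, c(8L, 8L, 8L))
})

test_that("zeroed head weights give exactly sigmoid(0) = 0.5 everywhere", {
  m <- build_model(small_cfg())
  w <- get_weights(m)
  zeroed <- w[grep("^head", names(w))]
  zeroed <- lapply(zeroed, function(x) x * 0)
  set_weights(m, zeroed)
  out <- forward(m, array(0, c(2, 32, 32)))
  expect_equal(max(abs(out$p_myotube - 0.5)), 0)
  expect_equal(max(abs(out$p_centroid - 0.5)), 0)
})

test_that("residual blocks with a silenced branch are identity maps", {
  # neutralize every residual branch (bnB gain/shift = 0) in a deep and a
  # shallow model, then share all non-residual weights: the outputs must
  # coincide, proving the skip path is a pure identity
  deep <- build_model(small_cfg(n_residual_blocks = 4L))
  shallow <- build_model(small_cfg(n_residual_blocks = 1L))
  silence <- function(m) {
    w <- get_weights(m)
    res_scale <- w[grep("bnB\\.(gamma|beta)$", names(w))]
    set_weights(m, lapply(res_scale, function(x) x * 0))
    m
  }
  silence(deep); silence(shallow)
  shared <- get_weights(shallow)
  shared <- shared[!grepl("^res", names(shared))]
  set_weights(deep, shared)
  x <- array(runif(2 * 32 * 32), c(2, 32, 32))
  expect_equal(forward(deep, x)$p_myotube, forward(shallow, x)$p_myotube,
               tolerance = 1e-12)
})

test_that("bce_loss matches the analytic values and a per-pixel loop oracle", {
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(bce_loss(t * 0 + 0.5, t), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(matrix(0.9), matrix(1)), -log(0.9), tolerance = 1e-12)
  expect_lte(bce_loss(t, t), 1.001e-7)           # perfect prediction
  set.seed(31)
  for (i in 1:5) {
    p <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(bce_loss(p, y), bce_loop(p, y), tolerance = 1e-12)
  }
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 2, 3)), "mismatch")
})

test_that("total_loss is the lambda-weighted sum of the per-class terms", {
  set.seed(5)
  outs <- list(p_myotube = matrix(runif(16), 4), p_nuclei = matrix(runif(16), 4),
               p_centroid = matrix(runif(16), 4))
  tg <- list(myotube = matrix(rbinom(16, 1, .5), 4),
             nuclei = matrix(rbinom(16, 1, .5), 4),
             centroid = matrix(rbinom(16, 1, .5), 4))
  l <- total_loss(outs, tg)
  expect_equal(l$total, l$myotube + l$nuclei + l$centroid)
  l2 <- total_loss(outs, tg, lambda = c(2, 1, 1))
  expect_equal(l2$total, 2 * l$myotube + l$nuclei + l$centroid)
  # all-0.5 predictions: total is 3*ln(2) at unit weights
  half <- lapply(outs, function(x) x * 0 + 0.5)
  expect_equal(total_loss(half, tg)$total, 3 * log(2), tolerance = 1e-9)
  expect_error(total_loss(outs, tg, lambda = c(0, 1, 1)), "positive")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(12)
  m <- build_model(model_config(base_channels = 2L, n_residual_blocks = 1L,
                                seed = 3L))
  x <- array(runif(2 * 8 * 8), c(2, 8, 8))
  tg <- list(matrix(rbinom(64, 1, .4), 8, 8), matrix(rbinom(64, 1, .4), 8, 8),
             matrix(rbinom(64, 1, .2), 8, 8))
  lam <- c(1.5, 1, 0.7)
  w0 <- get_weights(m)
  g <- myoseg:::.net_gradients(m$ptr, x, tg[[1]], tg[[2]], tg[[3]], lam)
  loss_at <- function(w) {
    myoseg:::.net_set_weights(m$ptr, w)
    myoseg:::.net_train_step(m$ptr, x, tg[[1]], tg[[2]], tg[[3]], lam, FALSE)[1]
  }
  eps <- 1e-6
  for (nm in sample(names(w0), 8)) {
    j <- sample(length(w0[[nm]]), 1)
    wp <- w0; wp[[nm]][j] <- wp[[nm]][j] + eps
    wm <- w0; wm[[nm]][j] <- wm[[nm]][j] - eps
    num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    expect_equal(g[[nm]][j], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s[%d]", nm, j))
  }
})

test_that("one Adam step on a fixed batch decreases the total loss", {
  m <- build_model(small_cfg())
  x <- array(runif(2 * 32 * 32), c(2, 32, 32))
  tg <- list(matrix(rbinom(1024, 1, .3), 32), matrix(rbinom(1024, 1, .3), 32),
             matrix(rbinom(1024, 1, .1), 32))
  before <- myoseg:::.net_train_step(m$ptr, x, tg[[1]], tg[[2]], tg[[3]],
                                     c(1, 1, 1), TRUE)[1]
  after <- myoseg:::.net_train_step(m$ptr, x, tg[[1]], tg[[2]], tg[[3]],
                                    c(1, 1, 1), FALSE)[1]
  expect_lt(after, before)
})

test_that("training is seeded and reproducible end to end", {
  ds <- lapply(1:2, function(s) {
    sc <- generate_scene(scene_spec(height = 64, width = 64, n_tubes = 2,
                                    n_nuclei = 4, seed = s))
    list(x = sc$image$pixels, labels = make_labels_from_truth(sc$truth))
  })
  run <- function() {
    m <- build_model(small_cfg())
    train_model(m, ds, epochs = 2)$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1$loss_total, h2$loss_total)
  expect_true(all(is.finite(h1$loss_total)))
  expect_lt(h1$loss_total[2], h1$loss_total[1])   # smoke: it learns
})

test_that("checkpoints round-trip config and weights exactly", {
  m <- build_model(small_cfg())
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  x <- array(runif(2 * 32 * 32), c(2, 32, 32))
  expect_identical(forward(m, x)$p_nuclei, forward(m2, x)$p_nuclei)
})

test_that("parameter counts grow strictly with residual depth and match closed form", {
  counts <- sapply(2:8, function(d) {
    cfg <- small_cfg(n_residual_blocks = d)
    m <- build_model(cfg)
    expect_equal(n_params(m), count_params(cfg))
    n_params(m)
  })
  expect_true(all(diff(counts) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(n_down = 3), "2 downsampling")
  expect_error(model_config(n_residual_blocks = 0), ">= 1")
  expect_error(model_config(lambda = c(1, -1, 1)), "positive")
})
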