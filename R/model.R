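#' Configuration of the three-headed residual encoder-decoder
#'
#' The network is: two stride-2 3x3 conv downsampling blocks (instance
#' norm + ReLU, channels 2 -> `base` -> `2*base`), a stack of
#' `n_residual_blocks` residual blocks (3x3 conv, batch norm, ReLU, 3x3
#' conv, batch norm, identity skip), two stride-2 3x3 transposed-conv
#' upsampling blocks (instance norm + LeakyReLU), and three class heads
#' (5x5 conv + sigmoid), one per output: myotube mask, nuclei mask,
#' nuclei centroid.
#'
#' With the default `strict_128 = FALSE`, a 1x1 projection doubles the
#' channels (`2*base` -> `4*base`) before the residual stack and a 1x1
#' projection reduces them back afterwards, so that with `base = 64` the
#' residual stack runs at 256 channels while the up-blocks see 128;
#' `strict_128 = TRUE` keeps `2*base` channels throughout instead.
#'
#' @param in_channels Input channels (2: myotube + nuclei stains).
#' @param base_channels Channels after the first downsampling block
#'   (64 at full scale; smaller values give a proportionally thinner
#'   network for CPU-scale experiments).
#' @param n_down Number of downsampling stages; the architecture is
#'   defined for exactly 2 and other values are rejected.
#' @param n_residual_blocks Residual stack depth (default 5; sweep 2..8
#'   with [ablate_residual_depth()]).
#' @param n_heads Number of class heads (3).
#' @param head_kernel Kernel size of the head convs (5).
#' @param lr,beta1,beta2 Adam settings (defaults 0.001, 0.5, 0.999).
#' @param epochs,batch_size Training loop defaults.
#' @param lambda Positive per-class loss weights (myotube, nuclei,
#'   centroid).
#' @param strict_128 See Description.
#' @param seed Weight-initialization seed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(in_channels = 2L, base_channels = 64L, n_down = 2L,
                         n_residual_blocks = 5L, n_heads = 3L,
                         head_kernel = 5L, lr = 0.001, beta1 = 0.5,
                         beta2 = 0.999, epochs = 30L, batch_size = 1L,
                         lambda = c(1, 1, 1), strict_128 = FALSE,
                         seed = 1L) {
  if (n_down != 2L)
    stop("the architecture defines exactly 2 downsampling stages; n_down = ",
         n_down, " is not supported")
  if (n_residual_blocks < 1) stop("n_residual_blocks must be >= 1")
  if (any(lambda <= 0)) stop("lambda weights must be strictly positive")
  if (n_heads != 3L) stop("the model has exactly 3 class heads")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_down = 2L,
                 n_residual_blocks = as.integer(n_residual_blocks),
                 n_heads = 3L, head_kernel = as.integer(head_kernel),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda = as.numeric(lambda),
                 strict_128 = isTRUE(strict_128),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build (and initialize) the segmentation network
#'
#' Convolution weights use Kaiming-normal initialization; biases start at
#' zero, batch-norm gains at one.
#'
#' @param cfg A [model_config()].
#' @return Object of class `myoseg_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  ptr <- .net_create(cfg)
  .net_init(ptr, cfg$seed)
  structure(list(ptr = ptr, cfg = cfg), class = "myoseg_model")
}

#' @export
print.myoseg_model <- function(x, ...) {
  cat(sprintf(paste0("myoseg_model: base %d, %d residual blocks%s, ",
                     "%s parameters\n"),
              x$cfg$base_channels, x$cfg$n_residual_blocks,
              if (x$cfg$strict_128) " (strict 128)" else "",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass: three probability maps for one image or patch
#'
#' @param model A `myoseg_model`.
#' @param x A [fluor_image()] or a `(2, H, W)` array; `H` and `W` must be
#'   divisible by 4 (two stride-2 stages). The network is fully
#'   convolutional, so any such size works.
#' @return `seg_outputs`: list of matrices `p_myotube`, `p_nuclei`,
#'   `p_centroid`, each `H x W` with values in (0, 1), plus the per-block
#'   output shapes of this pass in attribute `"shapes"`.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "myoseg_model"))
  px <- if (inherits(x, "fluor_image")) x$pixels else x
  if (length(dim(px)) != 3 || dim(px)[1] != model$cfg$in_channels)
    stop("input must be a (", model$cfg$in_channels, ", H, W) array")
  out <- .net_forward(model$ptr, px)
  attr(out, "shapes") <- .net_shapes(model$ptr)
  class(out) <- "seg_outputs"
  out
}

#' Binary cross-entropy between a probability map and a binary target
#'
#' Mean over all pixels of
#' `-(y*log(p) + (1-y)*log(1-p))`, with predictions clamped to
#' `[eps, 1-eps]` for numerical safety.
#'
#' @param pred Numeric matrix/array of probabilities.
#' @param target Binary matrix/array of the same shape.
#' @param eps Clamping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  check_same_shape(pred, target, "pred", "target")
  if (!all(target %in% c(0, 1))) stop("target must be binary {0,1}")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Weighted multi-task loss over the three heads
#'
#' `lambda[1]*L_myotube + lambda[2]*L_nuclei + lambda[3]*L_centroid`,
#' each term a [bce_loss()]; reduces to the plain sum at unit weights.
#'
#' @param outputs `seg_outputs` (or any list with the three maps).
#' @param targets Label triple (list `myotube`, `nuclei`, `centroid`).
#' @param lambda Strictly positive weight triple.
#' @return List with `total` and the three per-class losses.
#' @export
total_loss <- function(outputs, targets, lambda = c(1, 1, 1)) {
  if (any(lambda <= 0)) stop("lambda weights must be strictly positive")
  l1 <- bce_loss(outputs$p_myotube, targets$myotube)
  l2 <- bce_loss(outputs$p_nuclei, targets$nuclei)
  l3 <- bce_loss(outputs$p_centroid, targets$centroid)
  list(total = lambda[1] * l1 + lambda[2] * l2 + lambda[3] * l3,
       myotube = l1, nuclei = l2, centroid = l3)
}

#' Train the network on (patch, label-triple) pairs
#'
#' Plain Adam loop, one patch per optimizer step, epoch order reshuffled
#' from the model seed so runs are reproducible. If a validation set is
#' given, the weights with the best validation total loss are restored at
#' the end.
#'
#' @param model A `myoseg_model` (modified in place; also returned).
#' @param dataset List of samples, each a list with `x` (`(2,H,W)` array or
#'   `fluor_image`) and `labels` (label triple).
#' @param epochs Number of epochs (default from the model config).
#' @param validation Optional held-out list of samples, same shape.
#' @param verbose Print per-epoch losses.
#' @return List with `model` and `history` (data frame of per-epoch
#'   losses; attribute `"best_epoch"` when validation is used).
#' @export
train_model <- function(model, dataset, epochs = NULL, validation = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "myoseg_model"), length(dataset) > 0)
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  get_x <- function(s) if (inherits(s$x, "fluor_image")) s$x$pixels else s$x
  hist <- data.frame(epoch = integer(0), loss_total = numeric(0),
                     loss_myotube = numeric(0), loss_nuclei = numeric(0),
                     loss_centroid = numeric(0), val_total = numeric(0))
  best_val <- Inf
  best_w <- NULL
  best_epoch <- NA_integer_
  t0 <- proc.time()[["elapsed"]]
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(dataset))
      acc <- c(0, 0, 0, 0)
      for (i in ord) {
        s <- dataset[[i]]
        l <- .net_train_step(model$ptr, get_x(s), s$labels$myotube,
                             s$labels$nuclei, s$labels$centroid,
                             cfg$lambda, TRUE)
        if (!all(is.finite(l)))
          stop(sprintf(paste0("NaN/Inf loss at epoch %d, sample %d ",
                              "(lr = %g); training aborted"), ep, i, cfg$lr))
        acc <- acc + l
      }
      acc <- acc / length(dataset)
      val <- NA_real_
      if (!is.null(validation)) {
        vacc <- 0
        for (s in validation) {
          l <- .net_train_step(model$ptr, get_x(s), s$labels$myotube,
                               s$labels$nuclei, s$labels$centroid,
                               cfg$lambda, FALSE)
          vacc <- vacc + l[1]
        }
        val <- vacc / length(validation)
        if (val < best_val) {
          best_val <- val
          best_w <- .net_get_weights(model$ptr)
          best_epoch <- ep
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss_total = acc[1],
                                     loss_myotube = acc[2],
                                     loss_nuclei = acc[3],
                                     loss_centroid = acc[4],
                                     val_total = val))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  (myo %.4f nuc %.4f cen %.4f)%s",
                        ep, acc[1], acc[2], acc[3], acc[4],
                        if (is.na(val)) "" else sprintf("  val %.4f", val)))
    }
  })
  if (!is.null(best_w)) {
    .net_set_weights(model$ptr, best_w)
    attr(hist, "best_epoch") <- best_epoch
  }
  attr(hist, "wall_time_s") <- proc.time()[["elapsed"]] - t0
  attr(hist, "config") <- cfg
  list(model = model, history = hist)
}

#' Predict full-image probability maps, tiling when needed
#'
#' @param model A `myoseg_model`.
#' @param image A [fluor_image()].
#' @param tile_size If `NULL`, run a single forward pass when the image
#'   dims are divisible by 4; otherwise tile with this size.
#' @param overlap Tile overlap in px; overlapping predictions are averaged.
#' @return `seg_outputs` at full image size.
#' @export
predict_image <- function(model, image, tile_size = NULL, overlap = 0L) {
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  H <- dim(px)[2]; W <- dim(px)[3]
  if (is.null(tile_size)) {
    if (H %% 4 == 0 && W %% 4 == 0) return(forward(model, px))
    stop("image dims not divisible by 4; pass tile_size")
  }
  tl <- tile_for_inference(px, size = tile_size, overlap = overlap)
  preds <- lapply(tl$tiles, function(t) forward(model, t))
  out <- list()
  for (nm in c("p_myotube", "p_nuclei", "p_centroid"))
    out[[nm]] <- stitch_tiles(lapply(preds, `[[`, nm), tl$origins, H, W)
  class(out) <- "seg_outputs"
  out
}

#' Number of trainable parameters
#'
#' `n_params` queries the built network; `count_params` computes the same
#' quantity in closed form from a config (conv: `Cout*Cin*k^2 + Cout`;
#' batch norm: `2*C`; instance norm: none), so the two serve as
#' independent cross-checks.
#'
#' @param model A `myoseg_model`.
#' @return Parameter count (numeric scalar).
#' @export
n_params <- function(model) .net_n_params(model$ptr)

#' @rdname n_params
#' @param cfg A [model_config()].
#' @export
count_params <- function(cfg) {
  b <- cfg$base_channels
  cr <- if (cfg$strict_128) 2 * b else 4 * b
  conv <- function(cin, cout, k) cout * cin * k^2 + cout
  n <- conv(cfg$in_channels, b, 3) + conv(b, 2 * b, 3)        # down 1, 2
  if (!cfg$strict_128) n <- n + conv(2 * b, cr, 1)            # 1x1 in
  n <- n + cfg$n_residual_blocks * (2 * conv(cr, cr, 3) + 2 * (2 * cr))
  if (!cfg$strict_128) n <- n + conv(cr, 2 * b, 1)            # 1x1 out
  n <- n + conv(2 * b, 2 * b, 3) + conv(2 * b, b, 3)          # up 1, 2
  n + 3 * conv(b, 1, cfg$head_kernel)                         # heads
}

#' Get / set network weights (named list of matrices)
#' @param model A `myoseg_model`.
#' @export
get_weights <- function(model) .net_get_weights(model$ptr)

#' @rdname get_weights
#' @param weights Named list as returned by `get_weights`; partial lists
#'   update only the named parameters.
#' @export
set_weights <- function(model, weights) {
  .net_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a model checkpoint (config snapshot + weights)
#' @param model A `myoseg_model`.
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, weights = get_weights(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$cfg)
  set_weights(m, ck$weights)
  m
}

#' Residual-depth ablation sweep
#'
#' Builds (and optionally trains) one model per residual depth on shared
#' data, then reports parameter count, test time over the evaluation
#' images, and IoU/Dice of the myotube and nuclei heads.
#'
#' @param depths Integer vector of residual depths (default 2:8).
#' @param dataset Training samples (as in [train_model()]); `NULL` skips
#'   training (architecture-only sweep).
#' @param cfg Base [model_config()]; its `n_residual_blocks` is overridden.
#' @param eval_set Optional list of samples with `x` and `labels` used for
#'   IoU/Dice and test-time measurement; defaults to `dataset`.
#' @param epochs Training epochs per depth (default `cfg$epochs`).
#' @return Data frame with one row per depth: `depth`, `n_params`,
#'   `test_time_s`, `iou_myotube`, `dice_myotube`, `iou_nuclei`,
#'   `dice_nuclei`.
#' @export
ablate_residual_depth <- function(depths = 2:8, dataset = NULL,
                                  cfg = model_config(), eval_set = NULL,
                                  epochs = NULL) {
  eval_set <- eval_set %||% dataset
  rows <- lapply(depths, function(d) {
    dcfg <- cfg
    dcfg$n_residual_blocks <- as.integer(d)
    m <- build_model(dcfg)
    if (!is.null(dataset)) train_model(m, dataset, epochs = epochs)
    tt <- NA_real_
    iou_m <- dice_m <- iou_n <- dice_n <- NA_real_
    if (!is.null(eval_set)) {
      t0 <- proc.time()[["elapsed"]]
      preds <- lapply(eval_set, function(s)
        forward(m, if (inherits(s$x, "fluor_image")) s$x$pixels else s$x))
      tt <- proc.time()[["elapsed"]] - t0
      agg <- function(key, lab) {
        ccs <- mapply(function(p, s) {
          cc <- confusion((p[[key]] >= 0.5) * 1L, s$labels[[lab]])
          c(iou(cc), dice(cc))
        }, preds, eval_set)
        rowMeans(ccs)
      }
      am <- agg("p_myotube", "myotube")
      an <- agg("p_nuclei", "nuclei")
      iou_m <- am[1]; dice_m <- am[2]; iou_n <- an[1]; dice_n <- an[2]
    }
    data.frame(depth = d, n_params = count_params(dcfg), test_time_s = tt,
               iou_myotube = iou_m, dice_myotube = dice_m,
               iou_nuclei = iou_n, dice_nuclei = dice_n)
  })
  do.call(rbind, rows)
}
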