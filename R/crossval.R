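#' Image-level k-fold cross-validation folds
#'
#' Partitions images (never patches, to avoid leakage between folds) into
#' `k` disjoint test folds covering every image exactly once.
#'
#' @param n Number of images, or a vector of image identifiers.
#' @param k Number of folds (default 5; `k < 2` is rejected).
#' @param seed Partition seed; the same seed reproduces the same folds.
#' @return List of `k` vectors of image indices (or identifiers).
#' @export
crossval_folds <- function(n, k = 5L, seed = 1L) {
  ids <- if (length(n) == 1 && is.numeric(n)) seq_len(n) else n
  if (k < 2) stop("k-fold cross-validation requires k >= 2")
  if (length(ids) < k)
    stop(sprintf("need at least k = %d images, got %d", k, length(ids)))
  with_seed(seed, {
    ord <- sample(ids)
    split(ord, rep_len(seq_len(k), length(ord)))
  })
}

#' Compare a segmenter against the six auto-threshold baselines
#'
#' Evaluates myotube-channel segmentation IoU/Dice per method over a set
#' of scenes with ground truth, plus the number of skeleton branches each
#' method's mask produces (thresholding noisy/gradient images yields holes
#' and rough boundaries, which inflate spurious branches).
#'
#' @param scenes List of scenes, each a list with `image`
#'   ([fluor_image()]) and `truth` (with `myotube_mask`).
#' @param methods Threshold methods to include.
#' @param segmenter Optional function `(fluor_image) -> binary mask`
#'   reported as method `"learned"` (e.g. a trained model wrapper, or the
#'   ground truth itself as a ceiling).
#' @return Data frame with one row per method: `method`, `iou`, `dice`,
#'   `mean_branches` (averages over scenes).
#' @export
compare_methods <- function(scenes,
                            methods = c("isodata", "li", "mean", "minimum",
                                        "otsu", "yen"),
                            segmenter = NULL) {
  eval_masks <- function(get_mask, name) {
    ious <- dices <- nbr <- numeric(length(scenes))
    for (i in seq_along(scenes)) {
      sc <- scenes[[i]]
      mask <- get_mask(sc)
      cc <- confusion(mask, sc$truth$myotube_mask)
      ious[i] <- iou(cc)
      dices[i] <- dice(cc)
      nbr[i] <- length(extract_branches(skeletonize(mask))$branches)
    }
    data.frame(method = name, iou = mean(ious), dice = mean(dices),
               mean_branches = mean(nbr), stringsAsFactors = FALSE)
  }
  rows <- list()
  if (!is.null(segmenter))
    rows[[length(rows) + 1L]] <-
      eval_masks(function(sc) segmenter(sc$image), "learned")
  for (m in methods)
    rows[[length(rows) + 1L]] <- eval_masks(
      function(sc) threshold_segment(sc$image$pixels[1, , ], m), m)
  do.call(rbind, rows)
}
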