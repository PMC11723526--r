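#' Pixel confusion counts between a predicted and a true binary mask
#'
#' @param pred,truth Binary matrices of the same shape.
#' @return List with `TP`, `FP`, `FN`, `TN` (class `confusion_counts`).
#' @export
confusion <- function(pred, truth) {
  p <- as_binary(pred, "pred")
  t <- as_binary(truth, "truth")
  check_same_shape(p, t, "pred", "truth")
  tp <- sum(p == 1L & t == 1L)
  structure(list(TP = tp, FP = sum(p) - tp, FN = sum(t) - tp,
                 TN = sum(p == 0L & t == 0L)),
            class = "confusion_counts")
}

#' Intersection over union (Jaccard index)
#'
#' `TP / (TP + FP + FN)`. When both masks are empty the union is empty and
#' the score is defined as 1 (with a message); empty-vs-nonempty gives 0.
#'
#' @param cc A `confusion_counts` from [confusion()], or a pred/truth pair.
#' @param truth Optional; when given, `cc` and `truth` are masks.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(cc, truth = NULL) {
  if (!is.null(truth)) cc <- confusion(cc, truth)
  denom <- cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    message("both masks empty; IoU defined as 1")
    return(1.0)
  }
  cc$TP / denom
}

#' Dice coefficient
#'
#' `2TP / (2TP + FP + FN)`; 1 means perfect overlap, 0 none. Same
#' empty-mask convention as [iou()]. Algebraically
#' `Dice = 2*IoU / (1 + IoU)`.
#'
#' @inheritParams iou
#' @export
dice <- function(cc, truth = NULL) {
  if (!is.null(truth)) cc <- confusion(cc, truth)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) {
    message("both masks empty; Dice defined as 1")
    return(1.0)
  }
  2 * cc$TP / denom
}
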