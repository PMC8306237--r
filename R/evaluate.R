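check_masks <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("masks must share the same grid")
  invisible(NULL)
}

#' Dice similarity coefficient
#'
#' Overlap of two binary masks: `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param A,B logical matrices on the same grid, not both empty.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(A, B) {
  check_masks(A, B)
  sA <- sum(A)
  sB <- sum(B)
  if (sA + sB == 0) stop("Dice is undefined for two empty masks")
  2 * sum(A & B) / (sA + sB)
}

#' Jaccard similarity coefficient
#'
#' Overlap of two binary masks: `|A intersect B| / |A union B|`.
#' Related to Dice by `jaccard = dice / (2 - dice)`.
#'
#' @param A,B logical matrices on the same grid, union nonempty.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  check_masks(A, B)
  u <- sum(A | B)
  if (u == 0) stop("Jaccard is undefined for two empty masks")
  sum(A & B) / u
}

#' Confusion-matrix rates of a predicted mask
#'
#' Counts TP/FP/TN/FN of `pred` against `truth`, restricted to an
#' evaluation region, and reports precision `TP / (TP + FP)`, accuracy
#' `(TP + TN) / (TP + TN + FP + FN)` and recall `TP / (TP + FN)`. A rate
#' with a zero denominator is reported as `NA` and flagged in
#' `undefined`, never silently as 0.
#'
#' @param pred,truth logical matrices on the same grid.
#' @param region logical evaluation region; `NULL` (default) evaluates
#'   the full frame, which is the mode that background-dominated
#'   accuracies near 99% correspond to. Pass a breast mask to restrict
#'   the count universe to tissue.
#' @return List with counts `TP`, `FP`, `TN`, `FN`, rates `precision`,
#'   `accuracy`, `recall`, and `undefined`, a character vector naming any
#'   undefined rates.
#' @export
confusion_metrics <- function(pred, truth, region = NULL) {
  check_masks(pred, truth)
  if (is.null(region)) {
    region <- matrix(TRUE, nrow(pred), ncol(pred))
  }
  check_masks(pred, region)
  if (!any(region)) stop("evaluation region is empty")
  p <- pred[region]
  t <- truth[region]
  TP <- sum(p & t)
  FP <- sum(p & !t)
  FN <- sum(!p & t)
  TN <- sum(!p & !t)
  undefined <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      NA_real_
    } else num / den
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       precision = rate(TP, TP + FP, "precision"),
       accuracy = rate(TP + TN, TP + TN + FP + FN, "accuracy"),
       recall = rate(TP, TP + FN, "recall"),
       undefined = undefined)
}

#' Full segmentation evaluation report
#'
#' Dice, Jaccard and confusion rates of a predicted mask against the
#' ground truth in one call.
#'
#' @inheritParams confusion_metrics
#' @return List with `dice`, `jaccard` and the [confusion_metrics()]
#'   fields.
#' @export
evaluate_mask <- function(pred, truth, region = NULL) {
  cm <- confusion_metrics(pred, truth, region)
  c(list(dice = dice(pred, truth), jaccard = jaccard(pred, truth)), cm)
}
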