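#' Confusion counts of a binary segmentation against ground truth
#'
#' Pixelwise counts with "positive" meaning tumor: `TP` and `TN` are
#' correctly predicted tumor and background pixels, `FP` background
#' pixels predicted as tumor, `FN` tumor pixels predicted as background.
#'
#' @param pred logical/0-1 predicted tumor mask.
#' @param truth logical/0-1 ground-truth tumor mask, same shape.
#' @return A list of class `confusion_counts` with integer `TP`, `TN`,
#'   `FP`, `FN` summing to the number of pixels.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("`pred` and `truth` must share shape", call. = FALSE)
  }
  p <- as.logical(pred); t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) stop("masks must be binary without NA",
                                 call. = FALSE)
  structure(list(
    TP = sum(p & t), TN = sum(!p & !t),
    FP = sum(p & !t), FN = sum(!p & t)
  ), class = "confusion_counts")
}

#' Segmentation indices from confusion counts
#'
#' \deqn{accuracy = \frac{TP + TN}{TP + TN + FP + FN}, \quad
#'       precision = \frac{TP}{TP + FP},}
#' \deqn{recall = \frac{TP}{TP + FN}, \quad
#'       specificity = \frac{TN}{TN + FP}.}
#' An index whose denominator is zero is reported as `NA` (undefined,
#' distinct from 0) with a message.
#'
#' @param cc a [confusion()] result, or a list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @return Named numeric vector with `accuracy`, `precision`, `recall`,
#'   `specificity`, each in \[0, 1\] or `NA`.
#' @examples
#' seg_indices(confusion(c(1, 0), c(1, 0)))
#' @export
seg_indices <- function(cc) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(cc))) {
    stop("`cc` must contain TP, TN, FP, FN", call. = FALSE)
  }
  ratio <- function(num, den, name) {
    if (den == 0) {
      message(sprintf("seg_indices: %s undefined (zero denominator)", name))
      return(NA_real_)
    }
    num / den
  }
  with(cc, c(
    accuracy = ratio(TP + TN, TP + TN + FP + FN, "accuracy"),
    precision = ratio(TP, TP + FP, "precision"),
    recall = ratio(TP, TP + FN, "recall"),
    specificity = ratio(TN, TN + FP, "specificity")
  ))
}

#' Binarize a multi-cluster label map to a tumor mask
#'
#' Selects the tumor cluster either explicitly or as the cluster with the
#' brightest gray center (tumors are bright in FLAIR-like images).
#'
#' @param result a `segmentation_result`.
#' @param tumor_cluster explicit 1-based cluster index, or `NULL` to pick
#'   the brightest center.
#' @return A logical matrix (`TRUE` = tumor).
#' @export
tumor_mask <- function(result, tumor_cluster = NULL) {
  if (is.null(tumor_cluster)) {
    tumor_cluster <- which.max(result$centers$gray)
  }
  result$labels == as.integer(tumor_cluster)
}
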