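#' Rank-based ROC-AUC
#'
#' Area under the receiver-operator characteristic curve via the
#' Mann-Whitney statistic: the probability that a random positive is
#' scored above a random negative, with ties earning half credit
#' (midranks).
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined metric: ROC-AUC needs both classes", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two equal-shape binary masks;
#' two empty masks count as perfect agreement (1.0).
#'
#' @param pred,truth binary masks (numeric or logical, same shape);
#'   numeric input is binarised at 0.5.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      (is.null(dim(pred)) && length(pred) != length(truth)))
    stop("shape error: masks must have identical shape", call. = FALSE)
  a <- as.numeric(pred) > 0.5
  b <- as.numeric(truth) > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}
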