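# Evaluation metrics. Degenerate inputs yield NaN with a warning, never a
# silent number.

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with ties averaged. The positive class
#' is the larger of the two label values.
#'
#' @param scores Continuous classifier scores.
#' @param y Binary labels (two distinct values).
#' @return AUC in `[0, 1]`, or `NaN` (with a warning) if only one class is
#'   present.
#' @export
auc <- function(scores, y) {
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    warning("AUC undefined: need exactly two classes")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  pos <- y == classes[2]
  n1 <- sum(!pos); n2 <- sum(pos)
  (sum(r[pos]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' Classification accuracy
#'
#' @param pred Predicted class labels.
#' @param y True class labels.
#' @return Fraction of matching labels.
#' @export
accuracy <- function(pred, y) {
  if (length(pred) != length(y)) abort("`pred` and `y` differ in length")
  mean(pred == y)
}

#' Pearson correlation between estimated and true continuous labels
#'
#' @param z_hat Estimated labels.
#' @param z True labels.
#' @return Correlation coefficient, or `NaN` (with a warning) for
#'   zero-variance input.
#' @export
pearson <- function(z_hat, z) {
  if (stats::var(z_hat) == 0 || stats::var(z) == 0) {
    warning("correlation undefined: zero-variance input")
    return(NaN)
  }
  stats::cor(z_hat, z)
}
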