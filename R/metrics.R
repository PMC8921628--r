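#' Confusion-matrix statistics and rank AUC
#'
#' Shared by every validation harness. The positive class is always the
#' deleterious / functionally abnormal class `"D"`, so sensitivity is recall
#' on deleterious variants and specificity is recall on non-deleterious
#' ones. Statistics with a zero denominator are reported as `NA`
#' ("undefined"), never as zero.
#'
#' @name metrics
NULL

#' 2x2 confusion matrix
#'
#' @param truth,pred Vectors of class labels; values equal to `positive`
#'   count as the positive class, everything else as negative.
#' @param positive Positive-class label (default `"D"`).
#' @return Object of class `confusion` with integer fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @examples
#' confusion(c("D", "ND"), c("D", "ND"))
#' @export
confusion <- function(truth, pred, positive = "D") {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths (", length(truth), " vs ",
         length(pred), ")")
  }
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(
    list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
         fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)),
    class = "confusion"
  )
}

#' Construct a confusion matrix from counts
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("D", "ND"), predicted = c("D", "ND")))
  print(m)
  s <- summarize_confusion(x)
  cat(sprintf("accuracy %.2f%%  sensitivity %s  specificity %s\n",
              s$accuracy, fmt_pct(s$sensitivity), fmt_pct(s$specificity)))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f%%", x)

#' Summary statistics of a confusion matrix
#'
#' @param cm A `confusion` object.
#' @param digits Decimals used for the rounded `*_rounded` convenience
#'   fields (default 2, matching conventional reporting).
#' @return List with `accuracy`, `sensitivity`, `specificity` as
#'   percentages at full precision (`NA` when the denominator is zero), and
#'   the counts.
#' @examples
#' summarize_confusion(confusion_counts(tp = 157, tn = 26, fp = 0, fn = 7))
#' @export
summarize_confusion <- function(cm, digits = 2L) {
  stopifnot(inherits(cm, "confusion"))
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(
    n = n,
    accuracy = ratio(cm$tp + cm$tn, n),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp)
  )
  out$accuracy_rounded <- round(out$accuracy, digits)
  out$sensitivity_rounded <- round(out$sensitivity, digits)
  out$specificity_rounded <- round(out$specificity, digits)
  out
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half; computed from mid-ranks, so it is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric vector (higher = more positive/deleterious).
#' @param truth Class labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"D"`).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @examples
#' auc_rank(c(0.9, 0.4, 0.8, 0.1), c("D", "D", "ND", "ND"))  # 0.75
#' @export
auc_rank <- function(scores, truth, positive = "D") {
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  pos <- truth == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
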