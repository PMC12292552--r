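#' Confusion counts
#'
#' Counts of true/false positives/negatives with PD as the positive class.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) stopf("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from labels and predictions
#'
#' @param labels True labels (`"HC"`/`"PD"`).
#' @param predicted Predicted labels (`"HC"`/`"PD"`).
#' @return A [confusion_counts()].
#' @export
tally_confusion <- function(labels, predicted) {
  confusion_counts(tp = sum(labels == "PD" & predicted == "PD"),
                   tn = sum(labels == "HC" & predicted == "HC"),
                   fp = sum(labels == "HC" & predicted == "PD"),
                   fn = sum(labels == "PD" & predicted == "HC"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (PD recall), specificity (HC recall), precision,
#' and F1 (`2 * SN * P / (P + SN)`). Division-by-zero cases return 0 with
#' the `zero_division` attribute flagging which metrics were degenerate.
#'
#' @param counts A [confusion_counts()].
#' @return Named list `ac`, `sn`, `sp`, `p`, `f1`, all in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1) stopf("confusion counts sum to zero")
  flagged <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); return(0) }
    num / den
  }
  ac <- (tp + tn) / total
  sn <- safe_div(tp, tp + fn, "sn")
  sp <- safe_div(tn, tn + fp, "sp")
  p <- safe_div(tp, tp + fp, "p")
  f1 <- safe_div(2 * sn * p, p + sn, "f1")
  out <- list(ac = ac, sn = sn, sp = sp, p = p, f1 = f1)
  if (length(flagged)) {
    warning(sprintf("zero denominator for: %s (returned 0)",
                    paste(flagged, collapse = ", ")), call. = FALSE)
    attr(out, "zero_division") <- flagged
  }
  out
}

#' Sum confusion matrices across folds
#'
#' @param counts_list Non-empty list of [confusion_counts()].
#' @return A single [confusion_counts()] with elementwise sums.
#' @export
cumulative_confusion <- function(counts_list) {
  if (length(counts_list) < 1) stopf("need at least one fold result")
  stopifnot(all(vapply(counts_list, inherits, logical(1), "confusion_counts")))
  confusion_counts(tp = sum(vapply(counts_list, `[[`, numeric(1), "tp")),
                   tn = sum(vapply(counts_list, `[[`, numeric(1), "tn")),
                   fp = sum(vapply(counts_list, `[[`, numeric(1), "fp")),
                   fn = sum(vapply(counts_list, `[[`, numeric(1), "fn")))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (PD probability); AUC by the
#' trapezoidal rule, which equals the Mann-Whitney pairwise concordance
#' statistic with ties counted 1/2.
#'
#' @param scores Numeric vector of PD scores in `[0, 1]`.
#' @param labels True labels (`"HC"`/`"PD"`); both classes must be present.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  pos <- labels == "PD"
  if (!any(pos) || all(pos)) stopf("both classes must be present for ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Per-sentence-type accuracy
#'
#' @param labels True labels.
#' @param predicted Predicted labels.
#' @param sentence_ids Sentence type of each prediction.
#' @return data.frame `sentence_id`, `n`, `accuracy`, sorted by accuracy
#'   descending.
#' @export
per_sentence_accuracy <- function(labels, predicted, sentence_ids) {
  correct <- labels == predicted
  acc <- tapply(correct, sentence_ids, mean)
  n <- tapply(correct, sentence_ids, length)
  out <- data.frame(sentence_id = names(acc), n = as.integer(n),
                    accuracy = as.numeric(acc), stringsAsFactors = FALSE)
  out[order(-out$accuracy, out$sentence_id), , drop = FALSE]
}
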