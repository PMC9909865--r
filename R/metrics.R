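# Interpretation-score inference, thresholding, and the eight-metric
# evaluation panel: accuracy, precision, sensitivity, specificity, F1, MCC,
# ROC-AUC and PR-AUC.

#' Per-variant interpretation scores
#'
#' The interpretation score of a variant is its softmax probability of
#' oncogenicity under the trained discriminator (evaluation mode), a value
#' in `[0, 1]`.
#'
#' @param fit An `sgan_fit` (or `sgan_model`).
#' @param data An `encoded_matrix` or plain numeric matrix conforming to the
#'   model's column manifest.
#' @return Numeric vector of oncogenicity probabilities, named by variant id
#'   when available.
#' @export
interpretation_scores <- function(fit, data) {
  enc <- as_encoded(data)
  if (!is.null(fit$manifest) && !is.null(enc$manifest) &&
      !identical(fit$manifest$column, enc$manifest$column)) {
    stop_oncosgan("data columns do not match the model's manifest")
  }
  if (ncol(enc$matrix) != fit$discriminator$spec$input_dim) {
    stop_oncosgan("data has ", ncol(enc$matrix),
                  " columns but the model expects ",
                  fit$discriminator$spec$input_dim)
  }
  fw <- disc_forward(fit$discriminator, enc$matrix, training = FALSE,
                     want_caches = FALSE)
  p <- class_probabilities(fw$logits)[, "p_oncogenic"]
  names(p) <- enc$variant_id
  p
}

#' @export
predict.sgan_fit <- function(object, newdata, type = c("score", "class"),
                             cutoff = 0.5, ...) {
  type <- match.arg(type)
  sc <- interpretation_scores(object, newdata)
  if (type == "score") sc else classify_variants(sc, cutoff)
}

#' Threshold interpretation scores into class calls
#'
#' A variant is called oncogenic iff its score is strictly greater than the
#' cutoff (so a score exactly at the cutoff is called benign).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param cutoff Decision threshold in `[0, 1]` (default 0.5).
#' @return Character vector of `"oncogenic"` / `"benign"` calls.
#' @export
classify_variants <- function(scores, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ifelse(scores > cutoff, "oncogenic", "benign")
}

#' Confusion counts of binary calls against truth
#'
#' Oncogenic is the positive class.
#'
#' @param calls Character (or 1/2 index) predictions.
#' @param truth Character (or 1/2 index) true labels; unlabeled entries are
#'   an error.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(calls, truth) {
  p <- label_index(calls)
  t <- label_index(truth)
  if (length(p) != length(t)) stop_oncosgan("calls and truth differ in length")
  structure(list(tp = sum(p == 2L & t == 2L), fp = sum(p == 2L & t == 1L),
                 tn = sum(p == 1L & t == 1L), fn = sum(p == 1L & t == 2L)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Standard formulas: accuracy, precision, sensitivity (recall),
#' specificity, F1 and the Matthews correlation coefficient with numerator
#' `TP*TN - FP*FN`.  Ratios with a zero denominator are reported as `NaN`
#' with a warning.
#'
#' @param counts A `confusion_counts` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return A one-row data.frame with the six metric columns.
#' @export
binary_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop_oncosgan("confusion counts are all zero")
  ratio <- function(num, den, what) {
    if (is.nan(den) || den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  mcc_den <- sqrt(tn + fn) * sqrt(tn + fp) * sqrt(tp + fn) * sqrt(tp + fp)
  data.frame(
    accuracy = (tp + tn) / n,
    precision = precision,
    sensitivity = sensitivity,
    specificity = ratio(tn, fp + tn, "specificity"),
    f1 = ratio(2 * precision * sensitivity, precision + sensitivity, "F1"),
    mcc = ratio(tp * tn - fp * fn, mcc_den, "MCC"))
}

#' ROC-AUC by the rank (Mann-Whitney) statistic
#'
#' Ties count one half; equals the probability that a random oncogenic
#' variant outscores a random benign one.
#'
#' @param scores Numeric scores (higher = more oncogenic).
#' @param truth True labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  t <- label_index(truth)
  n_pos <- sum(t == 2L)
  n_neg <- sum(t == 1L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_oncosgan("ROC-AUC needs both classes in the truth vector")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[t == 2L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR-AUC by step-wise summation
#'
#' Walks the thresholds from the highest score down; the area is
#' `sum over threshold steps of (recall_i - recall_{i-1}) * precision_i`
#' (no linear interpolation between points).
#'
#' @param scores Numeric scores (higher = more oncogenic).
#' @param truth True labels; both classes must be present.
#' @return Area under the precision-recall curve in `[0, 1]`.
#' @export
pr_auc <- function(scores, truth) {
  t <- label_index(truth)
  n_pos <- sum(t == 2L)
  if (n_pos == 0L || sum(t == 1L) == 0L) {
    stop_oncosgan("PR-AUC needs both classes in the truth vector")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- (t[ord] == 2L)
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(s[-length(s)] != s[-1L], TRUE)   # last index of each tied block
  tp <- tp[keep]
  fp <- fp[keep]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Metric panel over a grid of cutoffs
#'
#' One row of the six threshold metrics per cutoff, plus the
#' threshold-independent ROC-AUC and PR-AUC (identical across rows).  The
#' reference sweep uses cutoffs 0.1 to 0.9 in steps of 0.1, plus 0.95.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param truth True labels.
#' @param cutoffs Sorted numeric cutoffs in `[0, 1]`.
#' @return Data.frame with one `MetricReport` row per cutoff.
#' @export
threshold_sweep <- function(scores, truth,
                            cutoffs = c(seq(0.1, 0.9, by = 0.1), 0.95)) {
  stopifnot(!is.unsorted(cutoffs), all(cutoffs >= 0), all(cutoffs <= 1))
  roc <- roc_auc(scores, truth)
  pr <- pr_auc(scores, truth)
  rows <- lapply(cutoffs, function(ct) {
    m <- suppressWarnings(
      binary_metrics(confusion_counts(classify_variants(scores, ct), truth)))
    cbind(data.frame(cutoff = ct), m,
          data.frame(roc_auc = roc, pr_auc = pr))
  })
  do.call(rbind, rows)
}

#' Full eight-metric report at one cutoff
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param truth True labels.
#' @param cutoff Decision threshold for the six threshold metrics.
#' @return One-row data.frame: cutoff, the six threshold metrics, ROC-AUC
#'   and PR-AUC.
#' @export
metric_report <- function(scores, truth, cutoff = 0.5) {
  m <- binary_metrics(confusion_counts(classify_variants(scores, cutoff),
                                       truth))
  cbind(data.frame(cutoff = cutoff), m,
        data.frame(roc_auc = roc_auc(scores, truth),
                   pr_auc = pr_auc(scores, truth)))
}
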