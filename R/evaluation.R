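# ---- evaluation --------------------------------------------------------

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j; row
#' sums equal the class supports.
#'
#' @param y_true,y_pred label vectors drawn from `classes`.
#' @param classes class names fixing the row/column order.
#' @return C x C integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = sort(unique(c(y_true, y_pred)))) {
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("labels outside the declared class set")
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  m <- table(true = ft, predicted = fp)
  matrix(as.integer(m), length(classes), length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Per-class precision/recall/F1 report
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean per
#' class, plus accuracy, macro (unweighted mean) and weighted
#' (support-weighted mean) averages. Undefined ratios (zero denominator)
#' are reported as 0 with a warning.
#'
#' @param y_true,y_pred label vectors.
#' @param classes class order.
#' @return `classification_report`: list with `per_class` data frame,
#'   `accuracy`, `macro_avg`, `weighted_avg`.
#' @export
classification_report <- function(y_true, y_pred,
                                  classes = sort(unique(c(y_true, y_pred)))) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  zero_div <- any(pred_tot == 0) || any(support == 0)
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe(tp, pred_tot)
  recall <- safe(tp, support)
  f1 <- safe(2 * precision * recall, precision + recall)
  if (zero_div) warning("zero-division in precision/recall set to 0")
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL, stringsAsFactors = FALSE)
  wmean <- function(x) sum(x * support) / sum(support)
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / sum(cm),
                 macro_avg = c(precision = mean(precision),
                               recall = mean(recall), f1 = mean(f1)),
                 weighted_avg = c(precision = wmean(precision),
                                  recall = wmean(recall), f1 = wmean(f1))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  df <- x$per_class
  df[2:4] <- lapply(df[2:4], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %.2f | macro P/R/F1 %.2f/%.2f/%.2f | weighted %.2f/%.2f/%.2f\n",
              x$accuracy, x$macro_avg[1], x$macro_avg[2], x$macro_avg[3],
              x$weighted_avg[1], x$weighted_avg[2], x$weighted_avg[3]))
  invisible(x)
}

# One-vs-rest ROC points with proper tie handling; returns fpr/tpr
# ordered from (0,0) to (1,1) and the trapezoidal AUC.
.roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(sum(lab), 1))
  fpr <- c(0, fp[last] / max(sum(1 - lab), 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

.pr_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  recall <- tp[last] / max(sum(lab), 1)
  precision <- tp[last] / (tp[last] + fp[last])
  list(recall = c(0, recall), precision = c(1, precision))
}

#' One-vs-rest PR and ROC curves with AUC
#'
#' Each class is scored against the rest using its predicted probability
#' column; ROC AUC is trapezoidal. Ties are grouped, so label-independent
#' (constant) scores give AUC 0.5. Classes absent from `y_true` are
#' reported as missing (`NA` AUC, empty curves).
#'
#' @param y_true label vector.
#' @param probabilities n x C matrix, columns ordered as `classes`.
#' @param classes class names.
#' @return named list per class: `roc` (fpr, tpr), `pr` (recall,
#'   precision), `auc`.
#' @export
classification_curves <- function(y_true, probabilities, classes) {
  if (ncol(probabilities) != length(classes))
    stop("probability columns must match classes")
  out <- lapply(seq_along(classes), function(ci) {
    lab <- as.integer(y_true == classes[ci])
    if (sum(lab) == 0 || sum(lab) == length(lab))
      return(list(roc = NULL, pr = NULL, auc = NA_real_, missing = TRUE))
    roc <- .roc_points(lab, probabilities[, ci])
    pr <- .pr_points(lab, probabilities[, ci])
    list(roc = roc[c("fpr", "tpr")], pr = pr, auc = roc$auc, missing = FALSE)
  })
  stats::setNames(out, classes)
}
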