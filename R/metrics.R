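#' Classification metrics report
#'
#' Computes the confusion matrix (argmax predictions), accuracy, Cohen's
#' kappa, per-class and macro-averaged precision/recall/F1, and the
#' macro-averaged one-vs-rest ROC AUC (trapezoidal integration of the ROC
#' curve built from the softmax scores). A class with no predicted positives
#' has precision 0 by convention; classes absent from the test set are
#' excluded from macro averages and AUC.
#'
#' @param probs trials x classes matrix of class probabilities (columns named
#'   with, or ordered as, `classes`).
#' @param truth true labels.
#' @param classes class label set (default the four MI classes).
#' @return object of class `metrics_report`: list with `confusion`
#'   (true x predicted counts), `accuracy`, `kappa`, `per_class` (data frame),
#'   `precision`, `recall`, `f1` (macro), `auc` (macro one-vs-rest), `n`.
#' @export
compute_metrics <- function(probs, truth, classes = mi_classes()) {
  probs <- as.matrix(probs)
  truth <- as.character(truth)
  if (nrow(probs) != length(truth))
    stop("probs rows and truth length differ")
  if (!all(truth %in% classes))
    stop("labels outside the class set: ",
         paste(setdiff(unique(truth), classes), collapse = ", "))
  if (ncol(probs) != length(classes))
    stop("probs must have one column per class")
  if (!is.null(colnames(probs))) probs <- probs[, classes, drop = FALSE]
  bad <- abs(rowSums(probs) - 1) > 1e-6 | probs < -1e-9
  if (any(bad))
    stop("probabilities must lie on the simplex (rows sum to 1)")
  pred <- classes[max.col(probs, ties.method = "first")]
  k <- length(classes)
  confusion <- table(factor(truth, classes), factor(pred, classes))
  names(dimnames(confusion)) <- c("true", "predicted")
  n <- length(truth)
  acc <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 1
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(confusion) > 0
  auc <- vapply(seq_len(k), function(j) {
    if (!present[j] || all(present[-j] == FALSE) && sum(present) == 1)
      return(NA_real_)
    roc_auc(probs[, j], truth == classes[j])
  }, 0)
  per_class <- data.frame(class = classes, precision = as.vector(prec),
                          recall = as.vector(rec), f1 = as.vector(f1),
                          auc = auc)
  structure(list(confusion = confusion, accuracy = acc, kappa = kappa,
                 per_class = per_class,
                 precision = mean(prec[present]), recall = mean(rec[present]),
                 f1 = mean(f1[present]), auc = mean(auc[present], na.rm = TRUE),
                 n = n), class = "metrics_report")
}

# one-vs-rest ROC AUC by trapezoid over the empirical ROC curve; ties in the
# score are grouped (diagonal segments), equivalent to the rank statistic
roc_auc <- function(score, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- roc_curve(score, positive)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' One-vs-rest ROC curve points
#'
#' @param score numeric classifier scores (higher = more positive).
#' @param positive logical truth.
#' @return data frame with `fpr` and `tpr`, from (0,0) to (1,1).
#' @export
roc_curve <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- positive[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)   # one point per distinct score
  data.frame(fpr = c(0, fp[last] / sum(!positive), 1),
             tpr = c(0, tp[last] / sum(positive), 1))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  accuracy %.4f  kappa %.4f  precision %.4f  recall %.4f  F1 %.4f  AUC %.4f\n",
              x$accuracy, x$kappa, x$precision, x$recall, x$f1, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Serialize a metrics report to JSON (and optionally the confusion to CSV)
#'
#' @param report a `metrics_report`.
#' @param path output `.json` path.
#' @param confusion_csv optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, confusion_csv = NULL) {
  jsonlite::write_json(
    list(n = report$n, accuracy = report$accuracy, kappa = report$kappa,
         precision = report$precision, recall = report$recall, f1 = report$f1,
         auc = report$auc,
         per_class = report$per_class,
         confusion = as.data.frame.matrix(unclass(report$confusion))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(confusion_csv))
    utils::write.csv(as.data.frame.matrix(unclass(report$confusion)),
                     confusion_csv)
  invisible(path)
}
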