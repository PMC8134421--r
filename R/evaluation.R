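#' Confusion matrix at a probability threshold
#'
#' A row is called positive when its probability is greater than or equal
#' to the threshold (ties count as positive calls).
#'
#' @param probs numeric vector of predicted probabilities.
#' @param labels binary vector (0/1 or logical) aligned with `probs`.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `confusion_matrix` with `tp`, `fn`, `fp`, `tn`
#'   and the threshold.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0L) stop("empty input", call. = FALSE)
  if (length(probs) != length(labels)) stop("probs and labels differ in length", call. = FALSE)
  y <- as.integer(as.logical(labels))
  pos <- probs >= threshold
  structure(list(
    tp = sum(pos & y == 1L), fn = sum(!pos & y == 1L),
    fp = sum(pos & y == 0L), tn = sum(!pos & y == 0L),
    threshold = threshold
  ), class = "confusion_matrix")
}

#' Build a confusion matrix from known counts
#'
#' Convenience constructor for published or externally computed counts.
#' @param tp,fn,fp,tn non-negative counts.
#' @param threshold threshold the counts were taken at.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, threshold = 0.5) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, threshold = threshold),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix at threshold %.2f\n", x$threshold))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
               dimnames = list(truth = c("positive", "negative"),
                               predicted = c("positive", "negative"))))
  invisible(x)
}

#' Threshold metrics from a confusion matrix
#'
#' Computes positive predictive value `tp/(tp+fp)`, negative predictive
#' value `tn/(tn+fn)`, sensitivity `tp/(tp+fn)` and specificity
#' `tn/(tn+fp)` at full precision. A metric with a zero denominator is
#' flagged undefined (`NA`), never silently 0. `round2()` applies the
#' half-up two-decimal display rounding used for reporting.
#'
#' @param cm a `confusion_matrix`.
#' @return list of class `metric_report` with `ppv`, `npv`, `sensitivity`,
#'   `specificity`, the undefined flags, and the counts.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    ppv = safe_div(cm$tp, cm$tp + cm$fp),
    npv = safe_div(cm$tn, cm$tn + cm$fn),
    sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
    specificity = safe_div(cm$tn, cm$tn + cm$fp),
    undefined = c(ppv = cm$tp + cm$fp == 0, npv = cm$tn + cm$fn == 0,
                  sensitivity = cm$tp + cm$fn == 0, specificity = cm$tn + cm$fp == 0),
    counts = cm
  ), class = "metric_report")
}

#' Half-up rounding for display
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @export
round2 <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PPV %.2f  NPV %.2f  sensitivity %.2f  specificity %.2f\n",
              round2(x$ppv), round2(x$npv), round2(x$sensitivity),
              round2(x$specificity)))
  if (!is.null(x$auroc_mean)) {
    cat(sprintf("AUROC %.3f (sd %.4f over %d fold models)\n",
                x$auroc_mean, x$auroc_sd, length(x$per_fold_auroc)))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, counting
#' ties as one half. Exactly equivalent to trapezoidal integration of the
#' ROC curve with explicit tie handling.
#'
#' @param probs numeric scores.
#' @param labels binary labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(probs, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(probs)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained ensemble on a labelled matrix
#'
#' AUROC is computed per outer-fold model and summarized as mean and
#' standard deviation; threshold metrics are computed on the mean-of-folds
#' probabilities. The matrix may come from a different cohort than the
#' training one (cross-cohort evaluation), as long as its columns match
#' the training columns.
#'
#' @param ensemble a [train_nested_cv()] result.
#' @param x encoded [feature_matrix()] or numeric matrix with matching
#'   columns.
#' @param labels binary labels aligned with rows.
#' @param threshold decision threshold (default 0.5).
#' @return a `metric_report` additionally carrying `auroc_mean`,
#'   `auroc_sd` and `per_fold_auroc`.
#' @export
evaluate_ensemble <- function(ensemble, x, labels, threshold = 0.5) {
  probs_fold <- predict_proba(ensemble, x, per_fold = TRUE)
  per_fold <- apply(probs_fold, 2, roc_auc, labels = labels)
  probs <- rowMeans(probs_fold)
  rep <- metrics_from_confusion(confusion_at_threshold(probs, labels, threshold))
  rep$auroc_mean <- mean(per_fold)
  rep$auroc_sd <- stats::sd(per_fold)
  rep$per_fold_auroc <- unname(per_fold)
  rep$probs <- probs
  rep
}
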