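#' Empirical ROC curve
#'
#' Standard empirical ROC over all distinct score thresholds (prediction rule
#' `score >= threshold` -> positive), from (0, 0) to (1, 1). The AUC equals
#' the Mann-Whitney concordance statistic with the midrank convention for
#' tied scores.
#'
#' @param scores numeric decision scores, higher favoring the positive class.
#' @param labels binary class labels.
#' @param positive the label counted as positive; default the second sorted
#'   unique label.
#' @return a `roc_curve`: list with `points` (data.frame `threshold`, `fpr`,
#'   `tpr`) and `auc` on the 0-1 scale.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  positive <- positive %||% default_positive(labels)
  y <- labels == positive
  if (!any(y) || all(y))
    stop("argument error: ROC needs both classes present")
  n_pos <- sum(y); n_neg <- sum(!y)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !y), numeric(1))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  structure(list(points = points, auc = auc_mw(scores, y),
                 positive = positive, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

# Mann-Whitney AUC with midranks (ties count 1/2).
auc_mw <- function(scores, y) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(y); n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.4f (%d pos / %d neg)>\n", x$auc, x$n_pos,
              x$n_neg))
  invisible(x)
}

#' Operating point closest to the (0, 1) ROC corner
#'
#' Selects the curve point minimizing the Euclidean distance
#' `sqrt(fpr^2 + (1 - tpr)^2)`; ties break toward the higher true-positive
#' rate, then the lower threshold.
#'
#' @param roc a [roc_curve()].
#' @return list with `threshold`, `fpr`, `tpr`, `distance`.
#' @export
closest_to_corner_threshold <- function(roc) {
  pts <- roc$points
  d2 <- pts$fpr^2 + (1 - pts$tpr)^2
  # compare at 12 significant digits so float noise cannot break exact ties
  ord <- order(signif(d2, 12), -pts$tpr, pts$threshold)
  best <- pts[ord[1L], ]
  list(threshold = best$threshold, fpr = best$fpr, tpr = best$tpr,
       distance = sqrt(d2[ord[1L]]))
}

#' Confusion-matrix metrics at a threshold
#'
#' Accuracy, sensitivity (on the positive/disease class) and specificity, in
#' percent, for the rule `score >= threshold` -> positive.
#'
#' @param scores numeric decision scores.
#' @param labels binary class labels.
#' @param threshold finite operating threshold.
#' @param positive label counted as positive.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent; `NA`
#'   with `not_applicable` flag when a class is absent), and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold, positive = NULL) {
  stopifnot(is.finite(threshold))
  positive <- positive %||% default_positive(labels)
  y <- labels == positive
  pred <- scores >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  list(accuracy = 100 * (tp + tn) / length(scores),
       sensitivity = sens, specificity = spec,
       not_applicable = c(sensitivity = tp + fn == 0,
                          specificity = tn + fp == 0),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Paired comparison of two correlated ROC curves (DeLong test)
#'
#' Tests whether two classifiers scored on the same samples have different
#' AUCs, using the placement-value covariance formulation: per-observation
#' placement values give the AUC as their mean, and the variance of the AUC
#' difference follows from the empirical covariances of the paired placements
#' within each class. The p-value is two-sided normal.
#'
#' @param scores_a,scores_b decision scores of the two models on the same
#'   samples.
#' @param labels shared binary class labels.
#' @param positive label counted as positive.
#' @return list with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
compare_rocs <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("alignment error: scores_a, scores_b and labels must have equal length")
  positive <- positive %||% default_positive(labels)
  y <- labels == positive
  if (!any(y) || all(y)) stop("argument error: both classes required")
  m <- sum(y); n <- sum(!y)
  va <- placements(scores_a, y)
  vb <- placements(scores_b, y)
  auc_a <- mean(va$v10); auc_b <- mean(vb$v10)
  s10 <- stats::cov(cbind(va$v10, vb$v10))
  s01 <- stats::cov(cbind(va$v01, vb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- auc_a - auc_b
  if (var_diff <= 0) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    return(list(p_value = p, auc_a = auc_a, auc_b = auc_b,
                z = if (abs(diff) < 1e-12) 0 else Inf * sign(diff)))
  }
  z <- diff / sqrt(var_diff)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = auc_a, auc_b = auc_b, z = z)
}

# Placement values: v10[i] = fraction of negatives below positive i,
# v01[j] = fraction of positives above negative j (midranks for ties).
placements <- function(scores, y) {
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  r_all <- rank(c(x, z), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(z, ties.method = "average")) / m
  list(v10 = v10, v01 = v01)
}

default_positive <- function(labels) {
  u <- sort(unique(as.character(labels[!is.na(labels)])))
  if (length(u) == 0L) stop("no labels available")
  u[length(u)]
}

#' Evaluation report for one model on one dataset
#'
#' Packages ROC AUC with threshold-based confusion metrics the way clinical
#' classification tables report them (percent scale; AUC x 100).
#'
#' @param scores decision scores.
#' @param labels binary labels.
#' @param threshold operating threshold; default the [closest_to_corner_threshold()]
#'   of this dataset's own ROC.
#' @param positive positive-class label.
#' @param task,model optional identifiers carried into the report.
#' @return an `eval_report` list with `accuracy`, `sensitivity`,
#'   `specificity`, `auc` (all percent scale), `threshold`, `n_pos`, `n_neg`.
#' @export
eval_report <- function(scores, labels, threshold = NULL, positive = NULL,
                        task = NULL, model = NULL) {
  positive <- positive %||% default_positive(labels)
  roc <- roc_curve(scores, labels, positive)
  if (is.null(threshold)) {
    corner <- closest_to_corner_threshold(roc)
    threshold <- corner$threshold
    if (!is.finite(threshold)) threshold <- max(scores) + 1
  }
  cm <- confusion_metrics(scores, labels, threshold, positive)
  structure(list(task = task, model = model,
                 accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, auc = 100 * roc$auc,
                 threshold = threshold, n_pos = roc$n_pos, n_neg = roc$n_neg,
                 positive = positive),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s%s: acc %.1f%% sens %.1f%% spec %.1f%% AUC %.1f>\n",
              if (!is.null(x$task)) paste0(" ", x$task) else "",
              if (!is.null(x$model)) paste0(" [", x$model, "]") else "",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
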