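#' Confusion counts and threshold metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and balanced
#' accuracy, their arithmetic mean — the headline metric under class
#' imbalance. Any single-class predictor (e.g. the all-negative baseline)
#' scores balanced accuracy exactly 0.5 on a mixed-label set.
#'
#' @param labels true binary labels (0/1), both classes present.
#' @param predictions predicted binary labels (0/1).
#' @return list: TP, FP, TN, FN, sensitivity, specificity,
#'   balanced_accuracy.
#' @export
confusion_metrics <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  if (length(unique(labels)) < 2)
    stop("balanced accuracy undefined: labels contain a single class")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a random positive scores above a random negative, ties
#' counted half — the Mann-Whitney U statistic normalised by `n1 * n0`,
#' computed from midranks. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param labels true binary labels (0/1), both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return scalar in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("ROC AUC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' Step-wise average precision: the sum over descending score thresholds
#' of precision times the recall increment. Tied scores are treated as a
#' single threshold. For random scores at prevalence pi, converges to pi.
#'
#' @param labels true binary labels (0/1), at least one positive.
#' @param scores numeric scores.
#' @return scalar in (0, 1].
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("PR AUC undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  thr_end <- cumsum(rle(s)$lengths)          # last index of each tie group
  tp <- cumsum(y)[thr_end]
  n_pred <- thr_end
  precision <- tp / n_pred
  recall <- tp / n1
  sum(precision * diff(c(0, recall)))
}

#' Bootstrap evaluation report
#'
#' Resamples regions with replacement `n_boot` times; replicates that lose
#' a class are redrawn (and counted) so exactly `n_boot` valid replicates
#' enter the percentile 2.5-97.5% confidence intervals. The comparison
#' against the all-negative baseline is `baseline_delta = balanced accuracy
#' - 0.5` per replicate, with a one-sided exceedance p-value: the fraction
#' of replicates with delta <= 0.
#'
#' @param labels true binary labels.
#' @param scores predicted probabilities.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed RNG seed; the report is a pure function of
#'   `(labels, scores, n_boot, seed)`.
#' @param threshold probability cutoff for the binary metrics.
#' @param metrics which metrics to report.
#' @return A `metric_report` list: `point` (named values), `ci` (data.table
#'   metric/ci_low/ci_high), `baseline_delta`, `p_value`, `n_redrawn`,
#'   `n_boot`.
#' @export
bootstrap_metrics <- function(labels, scores, n_boot = 1000, seed = 1L,
                              threshold = 0.5,
                              metrics = c("balanced_accuracy", "roc_auc",
                                          "pr_auc", "sensitivity",
                                          "specificity")) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  labels <- as.integer(labels)
  n <- length(labels)
  preds <- as.integer(scores >= threshold)

  eval_all <- function(lb, sc, pd) {
    cm <- confusion_metrics(lb, pd)
    out <- c(balanced_accuracy = cm$balanced_accuracy,
             sensitivity = cm$sensitivity, specificity = cm$specificity)
    if ("roc_auc" %in% metrics) out["roc_auc"] <- roc_auc(lb, sc)
    if ("pr_auc" %in% metrics) out["pr_auc"] <- pr_auc(lb, sc)
    out[metrics]
  }
  point <- eval_all(labels, scores, preds)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_boot, length(metrics),
                 dimnames = list(NULL, metrics))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      ix <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[ix])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    reps[b, ] <- eval_all(labels[ix], scores[ix], preds[ix])
  }
  ci <- data.table::data.table(
    metric = metrics,
    ci_low = apply(reps, 2, stats::quantile, 0.025, type = 7),
    ci_high = apply(reps, 2, stats::quantile, 0.975, type = 7))
  delta <- reps[, "balanced_accuracy"] - 0.5
  structure(list(point = point, ci = ci,
                 baseline_delta = unname(point["balanced_accuracy"] - 0.5),
                 p_value = mean(delta <= 0),
                 n_redrawn = n_redrawn, n_boot = n_boot,
                 replicates = reps),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Bootstrap metric report (n_boot =", x$n_boot, ")\n")
  for (m in x$ci$metric) {
    i <- match(m, x$ci$metric)
    cat(sprintf("  %-18s %.2f  (95%% CI %.2f-%.2f)\n", m, x$point[m],
                x$ci$ci_low[i], x$ci$ci_high[i]))
  }
  cat(sprintf("  baseline delta     %.2f  (one-sided p = %.3g)\n",
              x$baseline_delta, x$p_value))
  invisible(x)
}
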