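#' Evaluate probabilistic predictions against binary labels
#'
#' Computes the five metrics tracked by the bias protocol. The AUC is the
#' rank statistic (Mann-Whitney with midranks for ties), which for binary
#' labels coincides with the macro-averaged AUC. Sensitivity and specificity
#' use the conventional probability threshold of 0.5 on calibrated
#' probabilities; balanced accuracy is their mean. The Brier score is the
#' mean squared difference between the predicted positive-class probability
#' and the outcome — lower is better calibrated.
#'
#' @param probs positive-class probabilities in `[0, 1]`.
#' @param labels 0/1 labels; both classes must be present (the AUC is
#'   undefined otherwise).
#' @param threshold decision threshold for sensitivity/specificity.
#' @return a named list of class `metric_set` with elements `auc`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `brier`.
#' @export
evaluate <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("labels must contain both classes to evaluate")
  r <- rank(probs)   # midranks for ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred_pos <- probs >= threshold
  sens <- sum(pred_pos & labels == 1L) / n_pos
  spec <- sum(!pred_pos & labels == 0L) / n_neg
  structure(list(auc = auc, sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 brier = mean((probs - labels)^2)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | sens %.3f | spec %.3f | bal.acc %.3f | Brier %.3f\n",
    x$auc, x$sensitivity, x$specificity, x$balanced_accuracy, x$brier))
  invisible(x)
}

# mean of a list of metric_sets, per metric
.mean_metrics <- function(ms_list) {
  nm <- c("auc", "sensitivity", "specificity", "balanced_accuracy", "brier")
  out <- lapply(nm, function(f) mean(vapply(ms_list, `[[`, numeric(1), f)))
  names(out) <- nm
  structure(out, class = "metric_set")
}
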