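# Threshold metrics (accuracy, precision, recall, F1), rank-based ROC/AUC,
# and normal-approximation confidence intervals over repeated randomized runs.
# The severe class (label 1) is the positive class throughout.

#' Confusion counts at a probability threshold
#'
#' A record is predicted severe (positive) when its probability is `>=`
#' `threshold`; a probability exactly at the threshold maps to positive.
#'
#' @param labels Binary labels (0 = mild, 1 = severe).
#' @param probabilities Predicted severe-class probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list with integer fields `TP`, `TN`, `FP`,
#'   `FN` summing to `length(labels)`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- probabilities >= threshold
  structure(list(
    TP = sum(pred & labels == 1), TN = sum(!pred & labels == 0),
    FP = sum(pred & labels == 0), FN = sum(!pred & labels == 1)
  ), class = "confusion_counts")
}

degenerate_zero <- function(what) {
  warning("degenerate denominator in ", what, "; returning 0", call. = FALSE)
  0
}

#' Threshold classification metrics
#'
#' `Accuracy = (TP+TN)/(TP+TN+FP+FN)`, `Precision = TP/(TP+FP)`,
#' `Recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Degenerate denominators return 0
#' with a warning rather than an error so sweeps over tiny test sets complete.
#'
#' @param counts A [confusion_counts()] object.
#' @return A real in `[0, 1]`.
#' @export
cm_accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("all-zero confusion counts")
  (counts$TP + counts$TN) / tot
}

#' @rdname cm_accuracy
#' @export
cm_precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) return(degenerate_zero("precision (TP + FP = 0)"))
  counts$TP / d
}

#' @rdname cm_accuracy
#' @export
cm_recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(degenerate_zero("recall (TP + FN = 0)"))
  counts$TP / d
}

#' @rdname cm_accuracy
#' @export
cm_f1 <- function(counts) {
  p <- suppressWarnings(cm_precision(counts))
  r <- suppressWarnings(cm_recall(counts))
  if (p + r == 0) return(degenerate_zero("F1 (precision + recall = 0)"))
  2 * p * r / (p + r)
}

#' ROC curve and rank-based AUC
#'
#' AUC by the Mann-Whitney rank formulation with ties credited 0.5 (equal to
#' the probability a random severe case outranks a random mild case, plus half
#' the tie probability); the ROC is traced over all unique score thresholds,
#' starting at (0, 0) and ending at (1, 1). AUC is invariant to any strictly
#' increasing transform of the scores.
#'
#' @param labels Binary labels with at least one positive and one negative.
#' @param probabilities Scores (higher = more severe).
#' @return List with `auc` and `roc`, a data frame of
#'   `threshold, fpr, tpr` ordered by decreasing threshold.
#' @export
roc_auc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("ROC/AUC requires both classes present (got ", npos, " positive, ",
         nneg, " negative)")
  r <- rank(probabilities, ties.method = "average")
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probabilities[ord]
  last_of_run <- c(sc[-1] != sc[-length(sc)], TRUE)
  cum_tp <- cumsum(lab == 1)[last_of_run]
  cum_fp <- cumsum(lab == 0)[last_of_run]
  roc <- data.frame(threshold = c(Inf, sc[last_of_run]),
                    fpr = c(0, cum_fp / nneg),
                    tpr = c(0, cum_tp / npos))
  list(auc = auc, roc = roc)
}

#' Normal-approximation CI over repeated randomized runs
#'
#' `mean +/- 1.959964 * sd / sqrt(m)` (at the default 95% level) over `m`
#' repeated measurements of a metric.
#'
#' @param values Numeric vector of per-run metric values, `length >= 2`.
#' @param level Confidence level (default 0.95).
#' @return An `interval_summary` list: `m`, `mean`, `lower`, `upper`, `level`.
#' @export
repeated_ci <- function(values, level = 0.95) {
  m <- length(values)
  if (m < 2) stop("need at least 2 values for a confidence interval")
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- mean(values)
  half <- z * stats::sd(values) / sqrt(m)
  structure(list(m = m, mean = mu, lower = mu - half, upper = mu + half,
                 level = level),
            class = "interval_summary")
}

#' Per-client and macro metrics from a prediction record
#'
#' Computes accuracy, precision, recall, F1 and AUC per client from a
#' predictions data frame (`client, label, prob`, optionally `round` — the
#' final round is used), plus a `"macro"` row averaging the per-client
#' metrics.
#'
#' @param res Prediction data frame as produced by [run_federation()] or
#'   [run_baseline()].
#' @param threshold Decision threshold for the confusion metrics.
#' @return Data frame with columns
#'   `client, n, accuracy, precision, recall, f1, auc`.
#' @export
evaluate_predictions <- function(res, threshold = 0.5) {
  if (!nrow(res)) stop("no predictions to evaluate")
  if ("round" %in% names(res)) res <- res[res$round == max(res$round), ]
  one <- function(d) {
    cc <- confusion_counts(d$label, d$prob, threshold)
    auc <- tryCatch(roc_auc(d$label, d$prob)$auc, error = function(e) NA_real_)
    data.frame(n = nrow(d),
               accuracy = cm_accuracy(cc),
               precision = suppressWarnings(cm_precision(cc)),
               recall = suppressWarnings(cm_recall(cc)),
               f1 = suppressWarnings(cm_f1(cc)),
               auc = auc)
  }
  clients <- sort(unique(res$client))
  per <- do.call(rbind, lapply(clients, function(k)
    cbind(client = as.character(k), one(res[res$client == k, ]))))
  macro <- cbind(client = "macro",
                 data.frame(n = sum(per$n),
                            accuracy = mean(per$accuracy),
                            precision = mean(per$precision),
                            recall = mean(per$recall),
                            f1 = mean(per$f1),
                            auc = mean(per$auc)))
  out <- rbind(per, macro)
  rownames(out) <- NULL
  out
}
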