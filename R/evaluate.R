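# Performance metrics, ROC/AUC, summary-statistic t-tests, and the
# frozen-chain external-validation runner. The positive class for
# TP/precision/recall is CTL = 1 (switchable).

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return list of class `ConfusionCounts`.
#' @export
confusionCounts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN > 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "ConfusionCounts")
}

#' Metrics from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN); Precision = TP /
#' (TP + FP); Recall = TP / (TP + FN); F1 = 2 x Precision x Recall /
#' (Precision + Recall). A metric whose denominator is zero is
#' undefined and returned as NA with an `undefined` attribute naming
#' it.
#'
#' @param counts a [confusionCounts()] (or TP, given all four counts).
#' @param TN,FP,FN counts if `counts` is the TP count.
#' @return named numeric: accuracy, precision, recall, f1.
#' @examples
#' metricsFromCounts(confusionCounts(TP = 30, TN = 55, FP = 5, FN = 10))
#' @export
metricsFromCounts <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (!inherits(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, TN, FP, FN)
  undef <- character(0)
  acc <- with(counts, (TP + TN) / (TP + TN + FP + FN))
  prec <- if (counts$TP + counts$FP == 0) {
    undef <- c(undef, "precision"); NA_real_
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    undef <- c(undef, "recall"); NA_real_
  } else counts$TP / (counts$TP + counts$FN)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else f1FromPrecisionRecall(prec, rec)
  out <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' F1 from precision and recall
#' @param precision,recall scalars in [0, 1].
#' @return harmonic mean 2pr / (p + r).
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores in descending order; the AUC
#' is the trapezoidal area, which equals the Mann-Whitney concordance
#' U / (n0 x n1).
#'
#' @param probabilities scores for class 1.
#' @param labels 0/1 labels (both classes must be present).
#' @return list with `roc` (data.frame of FPR, TPR, starting at (0,0)
#'   and ending at (1,1)) and `auc`.
#' @export
rocAuc <- function(probabilities, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute a ROC curve")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  pr <- probabilities[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  keep <- c(diff(pr) != 0, TRUE)     # one point per distinct threshold
  tpr <- c(0, tp[keep] / n1)
  fpr <- c(0, fp[keep] / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Group summary statistics
#' @param n group size (>= 2).
#' @param mean,sd group mean and standard deviation (sd >= 0).
#' @return list of class `SummaryStats`.
#' @export
summaryStats <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "SummaryStats")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's pooled-variance t with df = nA + nB - 2 (pooling matches
#' the degrees of freedom conventionally reported with such contrasts).
#'
#' @param groupA,groupB [summaryStats()] objects.
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' twoSampleT(summaryStats(24, 3.87, 2.32), summaryStats(26, 32.92, 5.96))
#' @export
twoSampleT <- function(groupA, groupB) {
  stopifnot(inherits(groupA, "SummaryStats"),
            inherits(groupB, "SummaryStats"))
  df <- groupA$n + groupB$n - 2
  sp2 <- ((groupA$n - 1) * groupA$sd^2 + (groupB$n - 1) * groupB$sd^2) /
    df
  if (sp2 == 0) stop("zero pooled variance: t is undefined")
  t <- (groupA$mean - groupB$mean) /
    sqrt(sp2 * (1 / groupA$n + 1 / groupB$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Evaluate predictions against labels
#'
#' @param probabilities class-1 scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @param positive positive class for TP/precision/recall (default 1,
#'   i.e. CTL).
#' @return list of class `EvalReport`: `counts`, `metrics`, `roc`,
#'   `auc`.
#' @export
evalReport <- function(probabilities, labels, threshold = 0.5,
                       positive = 1) {
  pred <- as.integer(probabilities > threshold)
  labels <- as.integer(labels)
  pos <- as.integer(positive)
  counts <- confusionCounts(
    TP = sum(pred == pos & labels == pos),
    TN = sum(pred != pos & labels != pos),
    FP = sum(pred == pos & labels != pos),
    FN = sum(pred != pos & labels == pos))
  ra <- if (length(unique(labels)) >= 2) {
    sc <- if (pos == 1) probabilities else 1 - probabilities
    lb <- as.integer(labels == pos)
    rocAuc(sc, lb)
  } else list(roc = NULL, auc = NA_real_)
  structure(list(counts = counts, metrics = metricsFromCounts(counts),
                 roc = ra$roc, auc = ra$auc),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "EvalReport: acc %.4f  prec %.4f  rec %.4f  F1 %.4f  AUC %.4f\n",
    m["accuracy"], m["precision"], m["recall"], m["f1"], x$auc))
  with(x$counts, cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n",
                             TP, TN, FP, FN)))
  invisible(x)
}

#' External validation with the frozen training-time chain
#'
#' Applies the training-time preprocessing and feature chain (the
#' selection report's span, electrodes and feature combination) to
#' unseen recordings and scores the trained model's predictions. No
#' component is refitted.
#'
#' @param trained a `TrainedModel`.
#' @param recordings list of labelled [EEGRecording-class] objects
#'   containing the selected electrodes and at least the selected span
#'   after the trigger.
#' @param selection a `SelectionReport` (or a list with `span`,
#'   `electrodes`, `features`).
#' @param params [featureParams()].
#' @param filter apply [filterChain()] (default TRUE).
#' @return an `EvalReport`.
#' @export
externalValidate <- function(trained, recordings, selection,
                             params = featureParams(), filter = TRUE) {
  el <- canonicalizeLabels(selection$electrodes)
  for (rec in recordings) {
    miss <- setdiff(toupper(el), toupper(channelNames(rec)))
    if (length(miss))
      stop("subject '", subjectId(rec), "' is missing electrode(s) ",
           paste(miss, collapse = ", "))
  }
  rows <- lapply(recordings, function(rec) {
    if (filter) rec <- filterChain(rec)
    rec <- cropAndResample(rec, selection$span)
    wins <- vectorize(rec, selectedChannels = el)
    do.call(rbind, lapply(wins, function(w) {
      f <- extractFeatures(w, params = params)
      c(f$values, y = f$y)
    }))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  X <- as.matrix(tab[, selection$features, drop = FALSE])
  evalReport(predictProb(trained, X), tab$y)
}
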