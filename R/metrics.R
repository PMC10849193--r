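#' Confusion counts
#'
#' @slot TP,TN,FP,FN Non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  slots = c(TP = "integer", TN = "integer", FP = "integer", FN = "integer")
)

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@TP, object@TN, object@FP, object@FN) < 0L))
    "counts must be non-negative"
  else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP", object@TP, "TN", object@TN, "FP", object@FP,
      "FN", object@FN, "\n")
})

#' @param TP,TN,FP,FN Counts.
#' @rdname ConfusionCounts-class
#' @export
confusionCountsFrom <- function(TP, TN, FP, FN) {
  new("ConfusionCounts", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN))
}

#' Confusion counts from scores at a threshold
#'
#' Predicted positive exactly when \code{score >= threshold}.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) inputError("empty score vector")
  if (length(scores) != length(labels)) inputError("length mismatch")
  if (!all(labels %in% c(0, 1))) inputError("labels must be 0/1")
  pred <- scores >= threshold
  confusionCountsFrom(
    TP = sum(pred & labels == 1), TN = sum(!pred & labels == 0),
    FP = sum(pred & labels == 0), FN = sum(!pred & labels == 1)
  )
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " has a zero denominator; reported as 0")
    return(0)
  }
  num / den
}

#' Confusion-matrix classification metrics (percent scale)
#'
#' Specificity TN/(TN+FP), precision TP/(TP+FP), sensitivity TP/(TP+FN),
#' accuracy (TP+TN)/total and the Matthews correlation coefficient, all
#' multiplied by 100. Zero-denominator metrics are reported as 0 with a
#' warning. Values are returned at full precision; reports round
#' half-away-from-zero to 2 decimals.
#'
#' @param cc A \linkS4class{ConfusionCounts}.
#' @return Named numeric vector (Acc, Sens, Spec, Prec, MCC), percent scale.
#' @export
confusionMetrics <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  TP <- as.numeric(cc@TP); TN <- as.numeric(cc@TN)
  FP <- as.numeric(cc@FP); FN <- as.numeric(cc@FN)
  total <- TP + TN + FP + FN
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(
    Acc = 100 * safeRatio(TP + TN, total, "accuracy"),
    Sens = 100 * safeRatio(TP, TP + FN, "sensitivity"),
    Spec = 100 * safeRatio(TN, TN + FP, "specificity"),
    Prec = 100 * safeRatio(TP, TP + FP, "precision"),
    MCC = 100 * safeRatio(TP * TN - FP * FN, mccDen, "MCC")
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the full ROC sweep, computed through the
#' Mann-Whitney statistic with ties counted one half (midranks).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    inputError("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision integration: sweeping the threshold down
#' through the distinct score values, each recall increment is weighted by the
#' precision attained after including that score group (tied scores enter as
#' one group, so a constant score gives the positive prevalence).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (at least one positive).
#' @return AUPR in [0, 1].
#' @export
prAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L) inputError("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  groupEnds <- which(c(s[-1] != s[-length(s)], TRUE))
  cumTP <- cumsum(y)[groupEnds]
  cumN <- groupEnds
  precision <- cumTP / cumN
  recall <- cumTP / nPos
  dRecall <- diff(c(0, recall))
  sum(dRecall * precision)
}

#' Aggregate per-fold metrics into mean and sample-SD rows
#'
#' @param folds Per-fold metric data.frame (numeric columns).
#' @return Two-row data.frame: \code{Average} (mean) and \code{SD} (sample
#'   standard deviation, n-1 denominator).
#' @export
aggregateFolds <- function(folds) {
  num <- folds[vapply(folds, is.numeric, logical(1))]
  out <- rbind(colMeans(num), apply(num, 2, sd))
  out <- as.data.frame(out)
  rownames(out) <- c("Average", "SD")
  out
}

#' Format a fold report in the conventional table layout
#'
#' Percent metrics rounded half-away-from-zero to 2 decimals, AUC/AUPR to 4.
#'
#' @param report A \linkS4class{FoldReport}.
#' @return data.frame with fold rows plus Average and SD rows.
#' @export
formatFoldReport <- function(report) {
  stopifnot(is(report, "FoldReport"))
  tab <- rbind(report@folds, report@summary)
  for (col in intersect(c("Acc", "Sens", "Spec", "Prec", "MCC"),
                        colnames(tab)))
    tab[[col]] <- roundHalfUp(tab[[col]], 2)
  for (col in intersect(c("AUC", "AUPR"), colnames(tab)))
    tab[[col]] <- roundHalfUp(tab[[col]], 4)
  cbind(Fold = c(paste0("Fold", seq_len(nrow(report@folds))),
                 rownames(report@summary)),
        tab, row.names = NULL)
}

#' Write a fold report as TSV
#'
#' @param report A \linkS4class{FoldReport}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeFoldReport <- function(report, path) {
  write.table(formatFoldReport(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' ROC and PR curve points
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return List of two data.frames: \code{roc} (fpr, tpr) and \code{pr}
#'   (recall, precision), threshold swept over distinct scores.
#' @export
curvePoints <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  groupEnds <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[groupEnds]
  fp <- groupEnds - tp
  list(
    roc = data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos)),
    pr = data.frame(recall = tp / nPos, precision = tp / groupEnds)
  )
}
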