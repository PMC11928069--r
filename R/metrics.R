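# Confusion-matrix metrics and threshold-free ranking curves.

.checkBinary <- function(y, what = "y") {
  if (!all(y %in% c(0, 1))) stop(what, " must contain only 0/1 values")
}

#' Confusion counts for binary predictions
#'
#' @param y true labels (0/1).
#' @param yhat predicted labels (0/1), same length.
#' @return named integer vector with elements \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}; the four counts always sum to \code{length(y)}.
#' @examples
#' confusionCounts(c(1, 0), c(1, 0))
#' @export
confusionCounts <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  .checkBinary(y); .checkBinary(yhat, "yhat")
  c(tp = sum(y == 1 & yhat == 1), fp = sum(y == 0 & yhat == 1),
    tn = sum(y == 0 & yhat == 0), fn = sum(y == 1 & yhat == 0))
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, recall (sensitivity), precision, specificity and F1. Any 0/0
#' ratio returns 0 and is flagged rather than raising, so that large ablation
#' sweeps never abort on a degenerate split.
#'
#' @param counts named vector from \code{\link{confusionCounts}}.
#' @return one-row data.frame with columns \code{accuracy}, \code{recall},
#'   \code{precision}, \code{specificity}, \code{f1} and a logical
#'   \code{degenerate} flag.
#' @examples
#' summarizeCounts(c(tp = 2, fp = 1, tn = 3, fn = 2))
#' @export
summarizeCounts <- function(counts) {
  n <- sum(counts)
  if (n < 1) stop("counts must describe at least one sample")
  safe <- function(num, den) if (den == 0) 0 else num / den
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  rec <- safe(tp, tp + fn)
  prec <- safe(tp, tp + fp)
  spec <- safe(tn, tn + fp)
  f1 <- safe(2 * prec * rec, prec + rec)
  data.frame(
    accuracy = (tp + tn) / n, recall = rec, precision = prec,
    specificity = spec, f1 = f1,
    degenerate = (tp + fn) == 0 || (tp + fp) == 0 || (tn + fp) == 0
  )
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a random
#' positive is scored above a random negative, with ties counted one half.
#'
#' @param y true labels (0/1); both classes must be present.
#' @param p scores (higher means more positive).
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
#' @export
auroc <- function(y, p) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  .checkBinary(y)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("AUROC needs both classes present in y")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Area of the precision-recall step curve over the unique score thresholds
#' (prediction positive when score >= threshold), with no linear precision
#' interpolation: the area is \eqn{\sum_k (R_k - R_{k-1}) P_k} over thresholds
#' in decreasing order. Invariant under strictly increasing score transforms.
#'
#' @param y true labels (0/1); at least one positive required.
#' @param p scores.
#' @return AUPRC in [0, 1].
#' @examples
#' auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
#' @export
auprc <- function(y, p) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  .checkBinary(y)
  nPos <- sum(y == 1)
  if (nPos == 0) stop("AUPRC needs at least one positive in y")
  thr <- sort(unique(p), decreasing = TRUE)
  area <- 0; rPrev <- 0
  for (t in thr) {
    sel <- p >= t
    tp <- sum(y == 1 & sel)
    rec <- tp / nPos
    prec <- tp / sum(sel)
    area <- area + (rec - rPrev) * prec
    rPrev <- rec
  }
  area
}

#' Full evaluation report from scores
#'
#' Threshold metrics at the stated decision threshold (score >= threshold is
#' positive) plus AUROC and AUPRC from the raw scores. Ranking metrics are NA
#' when undefined (single-class truth), with the degenerate flag set.
#'
#' @param y true labels (0/1).
#' @param p predicted probabilities or scores.
#' @param threshold decision threshold (default 0.5).
#' @return one-row data.frame: accuracy, recall, precision, specificity, f1,
#'   auroc, auprc, degenerate.
#' @examples
#' metricsFromScores(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.2))
#' @export
metricsFromScores <- function(y, p, threshold = 0.5) {
  rep <- summarizeCounts(confusionCounts(y, as.integer(p >= threshold)))
  bothClasses <- length(unique(y)) == 2L
  rep$auroc <- if (bothClasses) auroc(y, p) else NA_real_
  rep$auprc <- if (sum(y == 1) > 0) auprc(y, p) else NA_real_
  rep$degenerate <- rep$degenerate || !bothClasses
  rep[, c("accuracy", "recall", "precision", "specificity", "f1",
          "auroc", "auprc", "degenerate")]
}
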