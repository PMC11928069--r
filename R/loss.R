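# Binary recall loss (BRLoss): cross-entropy with per-class weights tied to
# the current per-class batch recall,
#
#   L = -(1/N) sum_i [ w1 y_i log p_i + w0 (1 - y_i) log(1 - p_i) ],
#   w_c = (1 - Recall_c) + eps,
#
# where Recall_1 is the batch sensitivity and Recall_0 the batch specificity
# at the decision threshold, treated as constants (no derivative flows through
# them). A class whose recall is low gets a larger weight, so its samples pull
# harder on the logits; a class at perfect batch recall keeps only the small
# floor eps, preventing the learning signal from vanishing entirely.

#' Configuration for the binary recall loss
#'
#' @param decisionThreshold probability cut used to form the batch predictions
#'   that define the recalls; a tie (p equal to the threshold) classifies as
#'   positive.
#' @param weightFloor small non-negative constant added to each class weight
#'   so that a class at perfect batch recall retains a learning signal.
#' @param logClamp probabilities are clamped to
#'   [logClamp, 1 - logClamp] inside the logs, keeping the loss finite.
#' @return A named list of class \code{BrLossConfig}.
#' @examples
#' brLossConfig()
#' @export
brLossConfig <- function(decisionThreshold = 0.5, weightFloor = 1e-2,
                         logClamp = 1e-7) {
  stopifnot(decisionThreshold > 0, decisionThreshold < 1,
            weightFloor >= 0, logClamp > 0, logClamp < 0.5)
  structure(list(decisionThreshold = decisionThreshold,
                 weightFloor = weightFloor, logClamp = logClamp),
            class = "BrLossConfig")
}

#' Per-class recall of a batch
#'
#' Predictions are formed at the configured decision threshold (p >= threshold
#' classifies as positive). \code{recall1} is the sensitivity TP/(TP+FN) and
#' \code{recall0} the specificity TN/(TN+FP). A class absent from the batch
#' yields recall 1 by convention (vacuously perfect, so its loss weight falls
#' to the floor).
#'
#' @param y batch labels (0/1), length >= 1.
#' @param p predicted probabilities in [0, 1].
#' @param cfg a \code{\link{brLossConfig}}.
#' @return list with elements \code{recall1} and \code{recall0}.
#' @examples
#' batchRecall(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.8))
#' @export
batchRecall <- function(y, p, cfg = brLossConfig()) {
  if (length(y) < 1L) stop("batch must contain at least one sample")
  .checkBinary(y)
  yhat <- as.integer(p >= cfg$decisionThreshold)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  list(
    recall1 = if (nPos == 0) 1 else sum(y == 1 & yhat == 1) / nPos,
    recall0 = if (nNeg == 0) 1 else sum(y == 0 & yhat == 0) / nNeg
  )
}

.brWeights <- function(recalls, cfg) {
  list(w1 = (1 - recalls$recall1) + cfg$weightFloor,
       w0 = (1 - recalls$recall0) + cfg$weightFloor)
}

#' Binary recall loss of a batch
#'
#' @param y batch labels (0/1), length N >= 1.
#' @param p predicted probabilities in [0, 1].
#' @param recalls batch recalls from \code{\link{batchRecall}}, computed on
#'   this same batch and treated as constants.
#' @param cfg a \code{\link{brLossConfig}}.
#' @return scalar loss, finite for all inputs.
#' @examples
#' y <- c(1, 0); p <- c(0.5, 0.5)
#' cfg <- brLossConfig(weightFloor = 0)
#' brLoss(y, p, batchRecall(y, p, cfg), cfg)  # = log(2)/2
#' @export
brLoss <- function(y, p, recalls = batchRecall(y, p, cfg),
                   cfg = brLossConfig()) {
  n <- length(y)
  if (n < 1L) stop("batch must contain at least one sample")
  .checkBinary(y)
  w <- .brWeights(recalls, cfg)
  pc <- pmin(pmax(p, cfg$logClamp), 1 - cfg$logClamp)
  -(1 / n) * sum(w$w1 * y * log(pc) + w$w0 * (1 - y) * log(1 - pc))
}

#' Analytic per-sample gradient of the binary recall loss
#'
#' Gradient of \code{\link{brLoss}} with respect to the logits z (where
#' p = logistic(z)), with the recall weights held constant:
#' \deqn{dL/dz_i = (1/N) [ w_1 y_i (p_i - 1) + w_0 (1 - y_i) p_i ].}
#' For a positive sample the gradient is always <= 0 and its magnitude grows
#' as the batch sensitivity falls; for a negative sample it is >= 0 and grows
#' as the batch specificity falls — the mechanism that pushes the logits to
#' repair whichever class is currently under-recalled.
#'
#' @inheritParams brLoss
#' @return numeric vector of per-sample gradients dL/dz_i.
#' @export
brLossGrad <- function(y, p, recalls = batchRecall(y, p, cfg),
                       cfg = brLossConfig()) {
  n <- length(y)
  if (n < 1L) stop("batch must contain at least one sample")
  .checkBinary(y)
  w <- .brWeights(recalls, cfg)
  (1 / n) * (w$w1 * y * (p - 1) + w$w0 * (1 - y) * p)
}

#' Unweighted binary cross-entropy and its gradient
#'
#' The ablation baseline. \code{bceLoss} is the batch-mean cross-entropy with
#' the same probability clamp as \code{\link{brLoss}}; \code{bceGrad} is its
#' per-sample logit gradient (p - y)/N.
#'
#' @inheritParams brLoss
#' @return scalar loss, or numeric gradient vector.
#' @export
bceLoss <- function(y, p, cfg = brLossConfig()) {
  n <- length(y)
  if (n < 1L) stop("batch must contain at least one sample")
  .checkBinary(y)
  pc <- pmin(pmax(p, cfg$logClamp), 1 - cfg$logClamp)
  -(1 / n) * sum(y * log(pc) + (1 - y) * log(1 - pc))
}

#' @rdname bceLoss
#' @export
bceGrad <- function(y, p, cfg = brLossConfig()) {
  (p - y) / length(y)
}

# Batch loss + logit-gradient dispatcher used by the training loop.
.lossAndGrad <- function(name, y, p, cfg = brLossConfig()) {
  if (name == "brloss") {
    recalls <- batchRecall(y, p, cfg)
    list(loss = brLoss(y, p, recalls, cfg),
         grad = brLossGrad(y, p, recalls, cfg))
  } else if (name == "bce") {
    list(loss = bceLoss(y, p, cfg), grad = bceGrad(y, p, cfg))
  } else stop("unknown loss: ", name, " (use 'brloss' or 'bce')")
}
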