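# Training, evaluation and the ablation experimental design.

#' Training configuration
#'
#' Defaults follow the reference training regime (AdamW, learning rate
#' 2e-5, 200 epochs); \code{deskTrainingConfig} is the small preset used by
#' the tests, sized to converge on strongly separable synthetic data within
#' 30 epochs on one CPU.
#'
#' @param learningRate AdamW learning rate.
#' @param epochs number of passes over the training data.
#' @param batchSize minibatch size (the reference regime does not state one;
#'   16 is the default).
#' @param splitFraction train fraction for \code{\link{splitDataset}}.
#' @param seed seed controlling initialization and batch shuffling.
#' @param lossName "brloss" or "bce".
#' @param saEnabled build the network with spatial attention?
#' @param weightDecay AdamW decoupled weight decay (applied to convolution
#'   and dense weights, not biases).
#' @param lossCfg a \code{\link{brLossConfig}}.
#' @return named list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(learningRate = 2e-5, epochs = 200, batchSize = 16,
                           splitFraction = 0.8, seed = 1L,
                           lossName = "brloss", saEnabled = TRUE,
                           weightDecay = 0.01, lossCfg = brLossConfig()) {
  stopifnot(learningRate >= 0, epochs >= 1, batchSize >= 1,
            splitFraction > 0, splitFraction < 1,
            lossName %in% c("brloss", "bce"))
  structure(list(learningRate = learningRate, epochs = epochs,
                 batchSize = batchSize, splitFraction = splitFraction,
                 seed = as.integer(seed), lossName = lossName,
                 saEnabled = saEnabled, weightDecay = weightDecay,
                 lossCfg = lossCfg),
            class = "TrainingConfig")
}

#' @rdname trainingConfig
#' @param ... overrides passed on to \code{trainingConfig}.
#' @export
deskTrainingConfig <- function(...) {
  args <- list(...)
  defaults <- list(learningRate = 1e-3, epochs = 30, batchSize = 16)
  do.call(trainingConfig, utils::modifyList(defaults, args))
}

# -- AdamW -------------------------------------------------------------------

.adamwInit <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0L)
}

.adamwStep <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (grepl("_W", nm)) upd <- upd + wd * params[[nm]]  # decoupled decay
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# -- data preparation --------------------------------------------------------

#' Prepare model inputs from an ECG dataset
#'
#' Runs each report through the cleanup chain (or uses the inverted raw
#' intensities when \code{type = "raw"}, the unprocessed-input ablation arm)
#' and resizes to the model input size with bilinear filtering. ST-window
#' ground-truth masks, when present, are downsampled alongside for saliency
#' audits.
#'
#' @param ds an \linkS4class{EcgDataset}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @param inputH,inputW model input size.
#' @param type "processed" (cleanup chain) or "raw".
#' @return list with \code{x} (array inputH x inputW x 1 x N, values in
#'   [0, 1], waveform bright), \code{y} (labels), and \code{st} (array
#'   inputH x inputW x N of downsampled ST-window masks, or NULL).
#' @export
prepareInputs <- function(ds, cfg = preprocessConfig(), inputH = 64,
                          inputW = 64, type = c("processed", "raw")) {
  type <- match.arg(type)
  n <- length(ds)
  if (n < 1L) stop("dataset is empty")
  x <- array(0, c(inputH, inputW, 1, n))
  hasSt <- all(vapply(ds@reports, function(r) !is.null(r@masks$st), logical(1)))
  st <- if (hasSt) array(0, c(inputH, inputW, n)) else NULL
  for (i in seq_len(n)) {
    r <- ds@reports[[i]]
    plane <- if (type == "processed") {
      preprocessReport(r, cfg) * 1
    } else {
      (255 - r@pixels) / 255
    }
    x[, , 1, i] <- as.matrix(EBImage::resize(plane, w = inputH, h = inputW))
    if (hasSt)
      st[, , i] <- as.matrix(EBImage::resize(r@masks$st * 1,
                                             w = inputH, h = inputW))
  }
  list(x = x, y = labels(ds), st = st)
}

.subsetPrepared <- function(data, idx) {
  list(x = data$x[, , , idx, drop = FALSE], y = data$y[idx],
       st = if (!is.null(data$st)) data$st[, , idx, drop = FALSE] else NULL)
}

#' Stratified train/test split
#'
#' Random, label-stratified, disjoint and exhaustive split, reproducible by
#' seed: within each class, \code{round(fraction * n_class)} items go to the
#' training side, keeping both sides' positive proportions within one item of
#' the overall proportion.
#'
#' @param data an \linkS4class{EcgDataset}, a prepared-input list from
#'   \code{\link{prepareInputs}}, or a bare label vector (in which case index
#'   lists are returned).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test} of the same type
#'   as \code{data} (or index vectors for a label vector).
#' @export
splitDataset <- function(data, fraction = 0.8, seed = 1L) {
  y <- if (is(data, "EcgDataset")) labels(data)
       else if (is.list(data)) data$y else data
  n <- length(y)
  if (n < 2L) stop("need at least two items to split")
  idxTrain <- withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      ic <- which(y == cl)
      sample(ic, round(fraction * length(ic)))
    }))
  })
  idxTrain <- sort(idxTrain)
  idxTest <- setdiff(seq_len(n), idxTrain)
  if (length(idxTrain) == 0L || length(idxTest) == 0L)
    stop("split fraction leaves one side empty")
  if (is(data, "EcgDataset"))
    list(train = data[idxTrain], test = data[idxTest])
  else if (is.list(data))
    list(train = .subsetPrepared(data, idxTrain),
         test = .subsetPrepared(data, idxTest))
  else list(train = idxTrain, test = idxTest)
}

#' Resample a dataset to a target positive ratio
#'
#' Downsamples the majority side (without replacement, reproducibly) until
#' the positive proportion equals the target up to integer rounding; the
#' minority side is kept whole. A ratio already equal to the native
#' proportion returns the data unchanged.
#'
#' @param data as in \code{\link{splitDataset}}.
#' @param ratio target positive proportion in (0, 1).
#' @param seed integer seed.
#' @return data of the same type, subset to the target ratio (indices for a
#'   bare label vector).
#' @export
resampleToRatio <- function(data, ratio, seed = 1L) {
  y <- if (is(data, "EcgDataset")) labels(data)
       else if (is.list(data)) data$y else data
  stopifnot(ratio > 0, ratio < 1)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("resampling needs both classes present")
  native <- nPos / (nPos + nNeg)
  if (native > ratio) {          # too many positives: downsample positives
    keepPos <- round(ratio * nNeg / (1 - ratio))
    keepNeg <- nNeg
    if (keepPos < 1)
      stop(sprintf("ratio %.3f unattainable: would keep %d positives",
                   ratio, keepPos))
  } else {                       # downsample negatives
    keepNeg <- round(nPos * (1 - ratio) / ratio)
    keepPos <- nPos
    if (keepNeg < 1)
      stop(sprintf("ratio %.3f unattainable: would keep %d negatives",
                   ratio, keepNeg))
  }
  idx <- withr::with_seed(seed, {
    sort(c(sample(which(y == 1), keepPos), sample(which(y == 0), keepNeg)))
  })
  if (is(data, "EcgDataset")) data[idx]
  else if (is.list(data)) .subsetPrepared(data, idx)
  else idx
}

# -- training ----------------------------------------------------------------

#' Train the network
#'
#' Minibatch AdamW training, seeded end-to-end: the shuffle order of every
#' epoch derives from the training seed. Under \code{lossName = "brloss"} the
#' per-class batch recalls are recomputed for every batch and enter the loss
#' as detached weights.
#'
#' @param net a \linkS4class{SANet}.
#' @param x input array (H, W, 1/3, N) matching the network config.
#' @param y labels, length N.
#' @param cfg a \code{\link{trainingConfig}}.
#' @return list with \code{net} (trained) and \code{history} (data.frame of
#'   per-epoch mean loss).
#' @export
trainNet <- function(net, x, y, cfg = deskTrainingConfig()) {
  x <- .asInputArray(x, net@config)
  n <- dim(x)[4]
  if (length(y) != n) stop("labels do not match the number of images")
  .checkBinary(y)
  params <- net@params
  state <- .adamwInit(params)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- withr::with_seed((as.numeric(cfg$seed) * 1009 + ep) %% 2147483647,
                            sample.int(n, n))
    starts <- seq(1L, n, by = cfg$batchSize)
    epLoss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + cfg$batchSize - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      netTmp <- net; netTmp@params <- params
      fw <- netForward(netTmp, xb, wantCache = TRUE)
      lg <- .lossAndGrad(cfg$lossName, yb, fw$p, cfg$lossCfg)
      bw <- netBackward(netTmp, fw$cache, dz = lg$grad)
      stp <- .adamwStep(params, bw$grads, state, cfg$learningRate,
                        cfg$weightDecay)
      params <- stp$params; state <- stp$state
      epLoss <- epLoss + lg$loss * length(idx)
    }
    losses[ep] <- epLoss / n
  }
  net@params <- params
  list(net = net, history = data.frame(epoch = seq_len(cfg$epochs),
                                       loss = losses))
}

#' Evaluate a trained network
#'
#' Deterministic forward pass over the test set in evaluation mode, followed
#' by threshold metrics at the configured decision threshold plus AUROC and
#' AUPRC from the predicted probabilities.
#'
#' @param net a \linkS4class{SANet}.
#' @param x test input array.
#' @param y test labels.
#' @param threshold decision threshold; defaults to the network's configured
#'   threshold.
#' @return one-row data.frame as \code{\link{metricsFromScores}}, with the
#'   probabilities attached as attribute \code{"p"}.
#' @export
evaluateNet <- function(net, x, y, threshold = NULL) {
  x <- .asInputArray(x, net@config)
  n <- dim(x)[4]
  if (n < 1L) stop("test set is empty")
  if (length(y) != n) stop("labels do not match the number of images")
  if (is.null(threshold)) threshold <- net@config@threshold
  p <- numeric(n)
  for (s0 in seq(1L, n, by = 64L)) {
    idx <- s0:min(s0 + 63L, n)
    p[idx] <- netForward(net, x[, , , idx, drop = FALSE])$p
  }
  out <- metricsFromScores(y, p, threshold)
  attr(out, "p") <- p
  out
}

# -- ablation design ---------------------------------------------------------

.TOGGLES <- list(
  "none"        = list(saEnabled = FALSE, lossName = "bce"),
  "SA only"     = list(saEnabled = TRUE,  lossName = "bce"),
  "BRLoss only" = list(saEnabled = FALSE, lossName = "brloss"),
  "SA+BRLoss"   = list(saEnabled = TRUE,  lossName = "brloss")
)

#' Ablation configuration
#'
#' @param positiveRatios positive-class proportions to resample to; the
#'   string "native" keeps the data as generated. The reference design uses
#'   ratios 0.1 and 0.2.
#' @param repeats runs per (toggle, ratio) cell, each with a derived seed
#'   (the reference design repeats 30 times and averages).
#' @param toggles subset of "none", "SA only", "BRLoss only", "SA+BRLoss".
#' @param baseSeed master seed from which every run seed derives.
#' @return named list of class \code{AblationConfig}.
#' @export
ablationConfig <- function(positiveRatios = c(0.1, 0.2), repeats = 30,
                           toggles = names(.TOGGLES), baseSeed = 1L) {
  stopifnot(repeats >= 1, all(toggles %in% names(.TOGGLES)))
  num <- suppressWarnings(as.numeric(setdiff(positiveRatios, "native")))
  if (any(is.na(num)) || any(num <= 0) || any(num >= 1))
    stop("positiveRatios must lie in (0, 1) or be 'native'")
  structure(list(positiveRatios = positiveRatios, repeats = repeats,
                 toggles = toggles, baseSeed = as.integer(baseSeed)),
            class = "AblationConfig")
}

# Deterministic seed derivation: run seed = hash(baseSeed, toggle, ratio,
# repeat), kept within the 32-bit range R requires.
.deriveSeed <- function(base, ...) {
  v <- c(base, ...)
  s <- 0
  for (x in v) s <- (s * 69069 + as.numeric(x) * 40503 + 12345) %% 2147483647
  as.integer(s) + 1L
}

#' Run the ablation experimental design
#'
#' For every toggle (attention and loss on/off in the four combinations) and
#' every positive ratio: \code{repeats} times, resample to the ratio, split,
#' build, train and evaluate with a seed derived from the base seed, then
#' average the runs per cell. Single-run failures are recorded and skipped.
#'
#' @param data prepared inputs from \code{\link{prepareInputs}}.
#' @param cfg an \code{\link{ablationConfig}}.
#' @param training a \code{\link{trainingConfig}}; its \code{saEnabled} and
#'   \code{lossName} are overridden per toggle (the only two fields that vary
#'   between toggles).
#' @param netCfg base \code{\link{netConfig}}; \code{saEnabled} is overridden
#'   per toggle.
#' @return list of class \code{ExperimentReport}: \code{runs} (one row per
#'   run), \code{summary} (arithmetic mean per toggle x ratio), \code{toggles}
#'   (the wiring table), \code{config}, \code{failures}.
#' @export
ablationRun <- function(data, cfg = ablationConfig(),
                        training = deskTrainingConfig(),
                        netCfg = netConfig()) {
  runs <- list()
  failures <- list()
  for (ti in seq_along(cfg$toggles)) {
    tg <- cfg$toggles[ti]
    wiring <- .TOGGLES[[tg]]
    for (ri in seq_along(cfg$positiveRatios)) {
      ratio <- cfg$positiveRatios[ri]
      for (k in seq_len(cfg$repeats)) {
        # the seed deliberately excludes the toggle: repeat k of every arm
        # shares data, split and initialization, so arms are identically
        # seeded twins and the toggle is the only difference
        seed <- .deriveSeed(cfg$baseSeed, round(
          if (identical(ratio, "native")) 999 else as.numeric(ratio) * 1000),
          k)
        res <- tryCatch({
          dk <- if (identical(ratio, "native")) data
                else resampleToRatio(data, as.numeric(ratio), seed)
          sp <- splitDataset(dk, training$splitFraction, seed)
          nc <- netCfg; nc@saEnabled <- wiring$saEnabled
          tc <- training
          tc$saEnabled <- wiring$saEnabled
          tc$lossName <- wiring$lossName
          tc$seed <- seed
          net <- buildNet(nc, seed = seed)
          tr <- trainNet(net, sp$train$x, sp$train$y, tc)
          ev <- evaluateNet(tr$net, sp$test$x, sp$test$y)
          cbind(data.frame(toggle = tg, ratio = as.character(ratio),
                           rep = k, seed = seed), ev)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            toggle = tg, ratio = as.character(ratio), rep = k,
            message = conditionMessage(res))
        } else {
          runs[[length(runs) + 1L]] <- res
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  metricCols <- c("accuracy", "recall", "precision", "specificity", "f1",
                  "auroc", "auprc")
  summary <- if (!is.null(runs)) {
    agg <- stats::aggregate(runs[metricCols],
                            by = runs[c("toggle", "ratio")], FUN = mean)
    agg[order(match(agg$toggle, cfg$toggles), agg$ratio), ]
  } else NULL
  wiringTab <- do.call(rbind, lapply(cfg$toggles, function(tg)
    data.frame(toggle = tg, saEnabled = .TOGGLES[[tg]]$saEnabled,
               lossName = .TOGGLES[[tg]]$lossName)))
  structure(list(runs = runs, summary = summary, toggles = wiringTab,
                 config = list(ablation = cfg, training = training,
                               net = netCfg),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL),
            class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport:", if (!is.null(x$runs)) nrow(x$runs) else 0,
      "runs\n")
  if (!is.null(x$summary)) {
    cat("Cell means:\n")
    print(x$summary, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$failures))
    cat(nrow(x$failures), "failed runs recorded\n")
  invisible(x)
}
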