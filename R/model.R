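# ResNet-style backbone with CBAM-style spatial-attention gates after each of
# the four residual stages, a global-average-pool head and a single logit.

#' Network configuration
#'
#' @slot inputH,inputW input raster size in pixels (multiples of 4, >= 32).
#' @slot inputPlanes 1 (grayscale) or 3.
#' @slot scale "tiny" (stage widths 8/16/32/64, one basic block per stage,
#'   meant for 64 x 64 inputs so the whole pipeline runs on one CPU) or
#'   "full" (widths 64/128/256/512, 3/4/6/3 blocks, 224 x 224 inputs).
#' @slot saKernel odd kernel size of the spatial-attention convolution.
#' @slot saEnabled whether the four attention gates are inserted.
#' @slot threshold default decision threshold on the output probability.
#'
#' @exportClass NetConfig
setClass("NetConfig",
  representation(
    inputH = "integer", inputW = "integer", inputPlanes = "integer",
    scale = "character", saKernel = "integer", saEnabled = "logical",
    threshold = "numeric"
  )
)

setValidity("NetConfig", function(object) {
  msg <- character()
  if (!object@scale %in% c("tiny", "full"))
    msg <- c(msg, "scale must be 'tiny' or 'full'")
  if (object@saKernel %% 2L == 0L) msg <- c(msg, "saKernel must be odd")
  if (object@inputH %% 4L != 0L || object@inputW %% 4L != 0L ||
      object@inputH < 32L || object@inputW < 32L)
    msg <- c(msg, "input size must be a multiple of 4 and at least 32")
  if (!object@inputPlanes %in% c(1L, 3L))
    msg <- c(msg, "inputPlanes must be 1 or 3")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a network configuration
#'
#' @param inputH,inputW input size in pixels.
#' @param inputPlanes 1 or 3.
#' @param scale "tiny" or "full".
#' @param saKernel odd spatial-attention kernel size (default 7, the usual
#'   choice in convolutional block attention).
#' @param saEnabled insert the four spatial-attention gates?
#' @param threshold decision threshold on the predicted probability.
#' @return A \linkS4class{NetConfig}.
#' @examples
#' netConfig()                     # tiny 64 x 64 preset
#' netConfig(scale = "full", inputH = 224, inputW = 224)
#' @export
netConfig <- function(inputH = 64, inputW = 64, inputPlanes = 1,
                      scale = "tiny", saKernel = 7, saEnabled = TRUE,
                      threshold = 0.5) {
  new("NetConfig",
    inputH = as.integer(inputH), inputW = as.integer(inputW),
    inputPlanes = as.integer(inputPlanes), scale = scale,
    saKernel = as.integer(saKernel), saEnabled = saEnabled,
    threshold = threshold
  )
}

.archFor <- function(cfg) {
  if (cfg@scale == "tiny") {
    list(stemC = 8L, stemK = 3L, widths = c(8L, 16L, 32L, 64L),
         blocks = c(1L, 1L, 1L, 1L), strides = c(1L, 2L, 2L, 2L))
  } else {
    list(stemC = 64L, stemK = 7L, widths = c(64L, 128L, 256L, 512L),
         blocks = c(3L, 4L, 6L, 3L), strides = c(1L, 2L, 2L, 2L))
  }
}

#' A spatial-attention ECG image classifier
#'
#' Holds the configuration, the flat named list of parameter arrays, and an
#' architecture descriptor (the ordered module sequence used by
#' \code{\link{netAudit}}).
#'
#' @slot config a \linkS4class{NetConfig}.
#' @slot params named list of numeric arrays.
#' @slot arch architecture descriptor.
#'
#' @exportClass SANet
setClass("SANet",
  representation(config = "NetConfig", params = "list", arch = "list")
)

setMethod("show", "SANet", function(object) {
  a <- object@arch
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf(
    "SANet (%s): %dx%dx%d input, widths %s, %d spatial-attention blocks, %d parameters\n",
    object@config@scale, object@config@inputH, object@config@inputW,
    object@config@inputPlanes, paste(a$widths, collapse = "/"),
    if (object@config@saEnabled) 4L else 0L, np
  ))
})

.heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
}

#' Build the spatial-attention network
#'
#' Four residual stages (basic blocks; the first convolution of a stage
#' carries the stage stride and, with a 1 x 1 projection on the skip path,
#' any channel change), each followed — when enabled — by exactly one
#' spatial-attention gate positioned before the next stage; then global
#' average pooling and a single-logit head, with probabilities obtained
#' through the logistic function. Weights are He-initialized under the given
#' seed.
#'
#' @param cfg a \linkS4class{NetConfig}.
#' @param seed integer initialization seed.
#' @return A \linkS4class{SANet}.
#' @examples
#' net <- buildNet(netConfig(), seed = 1)
#' netAudit(net)
#' @export
buildNet <- function(cfg = netConfig(), seed = 1L) {
  a <- .archFor(cfg)
  params <- withr::with_seed(seed, {
    p <- list()
    kS <- a$stemK
    p$stem_W <- .heInit(c(kS, kS, cfg@inputPlanes, a$stemC),
                        kS * kS * cfg@inputPlanes)
    p$stem_b <- numeric(a$stemC)
    cin <- a$stemC
    for (i in 1:4) {
      cout <- a$widths[i]
      for (j in seq_len(a$blocks[i])) {
        s <- if (j == 1L) a$strides[i] else 1L
        cinB <- if (j == 1L) cin else cout
        pre <- sprintf("s%db%d_", i, j)
        p[[paste0(pre, "W1")]] <- .heInit(c(3, 3, cinB, cout), 9 * cinB)
        p[[paste0(pre, "b1")]] <- numeric(cout)
        p[[paste0(pre, "W2")]] <- .heInit(c(3, 3, cout, cout), 9 * cout)
        p[[paste0(pre, "b2")]] <- numeric(cout)
        if (s != 1L || cinB != cout) {
          p[[paste0(pre, "Wp")]] <- .heInit(c(1, 1, cinB, cout), cinB)
          p[[paste0(pre, "bp")]] <- numeric(cout)
        }
      }
      cin <- cout
      if (cfg@saEnabled) {
        k <- cfg@saKernel
        p[[sprintf("sa%d_W", i)]] <- .heInit(c(k, k, 2, 1), k * k * 2)
        # bias +2 opens the gate to ~0.88 at initialization, so the attention
        # network starts near its gate-free twin and learns to suppress
        p[[sprintf("sa%d_b", i)]] <- 2
      }
    }
    p$fc_W <- matrix(stats::rnorm(a$widths[4], 0, sqrt(1 / a$widths[4])),
                     1, a$widths[4])
    p$fc_b <- 0
    p
  })
  seqn <- c("stem", unlist(lapply(1:4, function(i)
    c(sprintf("stage%d", i), if (cfg@saEnabled) sprintf("sa%d", i)))),
    "gap", "fc")
  new("SANet", config = cfg, params = params,
      arch = c(a, list(sequence = seqn)))
}

#' Structural audit of a built network
#'
#' Walks the module sequence and reports, per position, the module kind. Used
#' to check the architecture contract: exactly one spatial-attention gate
#' after each of the four stages, before the next.
#'
#' @param net a \linkS4class{SANet}.
#' @return data.frame with columns \code{position}, \code{module},
#'   \code{kind}; attribute \code{saCount} gives the number of
#'   spatial-attention blocks.
#' @export
netAudit <- function(net) {
  seqn <- net@arch$sequence
  kind <- ifelse(grepl("^sa", seqn), "spatial_attention",
          ifelse(grepl("^stage", seqn), "residual_stage", seqn))
  out <- data.frame(position = seq_along(seqn), module = seqn, kind = kind)
  attr(out, "saCount") <- sum(kind == "spatial_attention")
  out
}

#' Saturate all spatial-attention gates open
#'
#' Forces the attention convolution to produce a large constant logit so the
#' logistic gate is 1 everywhere (to machine precision) and the network
#' computes the same function as its attention-free twin — the consistency
#' check behind the attention ablation.
#'
#' @param net a \linkS4class{SANet} built with attention enabled.
#' @param logit constant gate logit (default 20, giving a gate within 2e-9 of
#'   1).
#' @return the modified network.
#' @export
saturateGates <- function(net, logit = 20) {
  if (!net@config@saEnabled) stop("network was built without spatial attention")
  for (i in 1:4) {
    net@params[[sprintf("sa%d_W", i)]][] <- 0
    net@params[[sprintf("sa%d_b", i)]][] <- logit
  }
  net
}

.asInputArray <- function(x, cfg) {
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1, 1))
  else if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1, d[3]))
  d <- dim(x)
  if (d[1] != cfg@inputH || d[2] != cfg@inputW || d[3] != cfg@inputPlanes)
    stop(sprintf("input size %dx%dx%d does not match the configured %dx%dx%d",
                 d[1], d[2], d[3], cfg@inputH, cfg@inputW, cfg@inputPlanes))
  x
}

.blockForward <- function(x, p, pre, stride) {
  hasProj <- !is.null(p[[paste0(pre, "Wp")]])
  c1 <- .convForward(x, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]],
                     stride = stride, pad = 1L)
  a1 <- .relu(c1$y)
  c2 <- .convForward(a1, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]],
                     stride = 1L, pad = 1L)
  sk <- if (hasProj) {
    cp <- .convForward(x, p[[paste0(pre, "Wp")]], p[[paste0(pre, "bp")]],
                       stride = stride, pad = 0L)
    cp$y
  } else x
  y <- .relu(c2$y + sk)
  list(y = y, cache = list(c1 = c1$cache, a1 = a1, c2 = c2$cache,
                           proj = if (hasProj) cp$cache else NULL,
                           hasProj = hasProj, y = y))
}

.blockBackward <- function(dy, p, pre, cache, grads) {
  dpre <- .reluBackward(dy, cache$y)
  b2 <- .convBackward(dpre, p[[paste0(pre, "W2")]], cache$c2)
  grads[[paste0(pre, "W2")]] <- b2$dW
  grads[[paste0(pre, "b2")]] <- b2$db
  da1 <- .reluBackward(b2$dx, cache$a1)
  b1 <- .convBackward(da1, p[[paste0(pre, "W1")]], cache$c1)
  grads[[paste0(pre, "W1")]] <- b1$dW
  grads[[paste0(pre, "b1")]] <- b1$db
  dx <- b1$dx
  if (cache$hasProj) {
    bp <- .convBackward(dpre, p[[paste0(pre, "Wp")]], cache$proj)
    grads[[paste0(pre, "Wp")]] <- bp$dW
    grads[[paste0(pre, "bp")]] <- bp$db
    dx <- dx + bp$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

#' Forward pass
#'
#' Runs a batch of preprocessed rasters through the network. Deterministic for
#' fixed weights (the model has no stochastic layers).
#'
#' @param net a \linkS4class{SANet}.
#' @param x input: matrix (one image), (H, W, N) or (H, W, planes, N) array
#'   of intensities in [0, 1].
#' @param wantCache keep the intermediate activations needed by
#'   \code{\link{netBackward}} and \code{\link{gradCam}}?
#' @return list with \code{z} (logits, length N), \code{p} (probabilities,
#'   \code{p = logistic(z)}), and \code{cache} (NULL unless requested).
#' @export
netForward <- function(net, x, wantCache = FALSE) {
  cfg <- net@config
  p <- net@params
  a <- net@arch
  x <- .asInputArray(x, cfg)
  cache <- if (wantCache) list(blocks = list(), sa = list(),
                               stageOut = list()) else NULL

  st <- .convForward(x, p$stem_W, p$stem_b, stride = 2L,
                     pad = (a$stemK - 1L) %/% 2L)
  h <- .relu(st$y)
  pl <- .poolForward(h)
  cur <- pl$y
  if (wantCache) { cache$stem <- st$cache; cache$stemAct <- h; cache$pool <- pl$cache }

  for (i in 1:4) {
    for (j in seq_len(a$blocks[i])) {
      pre <- sprintf("s%db%d_", i, j)
      s <- if (j == 1L) a$strides[i] else 1L
      bf <- .blockForward(cur, p, pre, s)
      cur <- bf$y
      if (wantCache) cache$blocks[[pre]] <- bf$cache
    }
    if (cfg@saEnabled) {
      sf <- .saForward(cur, p[[sprintf("sa%d_W", i)]],
                       p[[sprintf("sa%d_b", i)]])
      cur <- sf$y
      if (wantCache) cache$sa[[i]] <- sf$cache
    }
    if (wantCache) cache$stageOut[[i]] <- cur
  }

  gp <- .gapForward(cur)
  z <- as.vector(p$fc_W %*% gp + p$fc_b)
  if (wantCache) { cache$gap <- gp; cache$lastDim <- dim(cur) }
  list(z = z, p = .sigmoid(z), cache = cache)
}

#' Backward pass
#'
#' Analytic gradients of \code{sum(dz * z)} with respect to every parameter
#' and to each stage output (the latter drive Grad-CAM).
#'
#' @param net a \linkS4class{SANet}.
#' @param cache cache from \code{netForward(..., wantCache = TRUE)}.
#' @param dz upstream gradient on the logits, length N.
#' @return list with \code{grads} (named like the parameters) and
#'   \code{stageGrads} (length 4, gradient at each stage output).
#' @export
netBackward <- function(net, cache, dz) {
  p <- net@params
  a <- net@arch
  grads <- list()
  dzm <- matrix(dz, nrow = 1)
  grads$fc_W <- dzm %*% t(cache$gap)
  grads$fc_b <- sum(dz)
  dgap <- t(p$fc_W) %*% dzm                      # (C, N)
  dcur <- .gapBackward(dgap, cache$lastDim)
  stageGrads <- vector("list", 4L)

  for (i in 4:1) {
    stageGrads[[i]] <- dcur
    if (net@config@saEnabled) {
      sb <- .saBackward(dcur, p[[sprintf("sa%d_W", i)]], cache$sa[[i]])
      grads[[sprintf("sa%d_W", i)]] <- sb$dW
      grads[[sprintf("sa%d_b", i)]] <- sb$db
      dcur <- sb$dx
    }
    for (j in rev(seq_len(a$blocks[i]))) {
      pre <- sprintf("s%db%d_", i, j)
      bb <- .blockBackward(dcur, p, pre, cache$blocks[[pre]], grads)
      grads <- bb$grads
      dcur <- bb$dx
    }
  }

  dh <- .poolBackward(dcur, cache$pool)
  dh <- .reluBackward(dh, cache$stemAct)
  sb <- .convBackward(dh, p$stem_W, cache$stem)
  grads$stem_W <- sb$dW
  grads$stem_b <- sb$db
  list(grads = grads, stageGrads = stageGrads)
}

#' Gradient-weighted class activation map
#'
#' Grad-CAM at one of the four stage outputs: channel activations are combined
#' with weights equal to the spatial mean of the logit gradient, rectified,
#' and rescaled to [0, 1] over the map. The overlay marks exactly the
#' locations whose upsampled value exceeds 0.4. When the gradient field is
#' identically zero the map is all-zero and flagged.
#'
#' @param net a \linkS4class{SANet}.
#' @param image single input (matrix or (H, W, planes) array, values in
#'   [0, 1]).
#' @param targetStage stage whose activations are visualized, 1-4 (default 4).
#' @return list of class \code{GradCamMap}: \code{values} (stage-resolution
#'   map in [0, 1]), \code{map} (bilinearly upsampled to input size),
#'   \code{overlay} (logical, \code{map > threshold}), \code{threshold}
#'   (0.4), \code{allZero}, \code{stage}.
#' @export
gradCam <- function(net, image, targetStage = 4L) {
  if (!targetStage %in% 1:4) stop("targetStage must be in 1..4")
  fw <- netForward(net, image, wantCache = TRUE)
  bw <- netBackward(net, fw$cache, dz = 1)
  A <- fw$cache$stageOut[[targetStage]]
  G <- bw$stageGrads[[targetStage]]
  d <- dim(A)
  alpha <- colMeans(matrix(G, nrow = d[1] * d[2]))    # per-channel weight
  cam <- matrix(matrix(A, nrow = d[1] * d[2]) %*% alpha, d[1], d[2])
  cam <- pmax(cam, 0)
  mx <- max(cam)
  allZero <- mx <= 0
  if (!allZero) cam <- cam / mx
  up <- as.matrix(EBImage::resize(cam, w = net@config@inputH,
                                  h = net@config@inputW))
  up <- pmin(pmax(up, 0), 1)
  structure(
    list(values = cam, map = up, overlay = up > 0.4, threshold = 0.4,
         allZero = allZero, stage = as.integer(targetStage)),
    class = "GradCamMap"
  )
}

#' @export
print.GradCamMap <- function(x, ...) {
  cat(sprintf(
    "GradCamMap: stage %d, %dx%d map, %d cells above %.1f%s\n",
    x$stage, nrow(x$values), ncol(x$values), sum(x$overlay), x$threshold,
    if (x$allZero) " (all-zero gradient fallback)" else ""
  ))
  invisible(x)
}
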