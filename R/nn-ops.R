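# Minimal CNN primitives in base R with BLAS-backed im2col convolutions.
#
# Tensor convention: 4-d numeric arrays with dim (H, W, C, N) — height, width,
# channels, batch. Weights of a k x k convolution are stored as arrays
# (k, k, Cin, Cout). All layers return both the output and the cache the
# analytic backward pass needs; nothing here is exported.

.convForward <- function(x, W, b, stride = 1L, pad = 1L) {
  y <- .convFwdCpp(x, W, as.numeric(b), as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, stride = as.integer(stride),
                           pad = as.integer(pad)))
}

.convBackward <- function(dy, W, cache) {
  .convBwdCpp(cache$x, W, dy, cache$stride, cache$pad)
}

.relu <- function(x) pmax(x, 0)
.reluBackward <- function(dy, y) dy * (y > 0)

# 2x2 max pooling, stride 2; even H and W assumed (enforced by the configs).
.poolForward <- function(x) {
  d <- dim(x)
  o <- x[seq(1, d[1], 2), , , , drop = FALSE]
  e <- x[seq(2, d[1], 2), , , , drop = FALSE]
  m1 <- pmax(o, e)
  rowTop <- o >= e
  oc <- m1[, seq(1, d[2], 2), , , drop = FALSE]
  ec <- m1[, seq(2, d[2], 2), , , drop = FALSE]
  y <- pmax(oc, ec)
  colLeft <- oc >= ec
  list(y = y, cache = list(rowTop = rowTop, colLeft = colLeft, xDim = d))
}

.poolBackward <- function(dy, cache) {
  d <- cache$xDim
  dm1 <- array(0, c(d[1] %/% 2, d[2], d[3], d[4]))
  dm1[, seq(1, d[2], 2), , ] <- dy * cache$colLeft
  dm1[, seq(2, d[2], 2), , ] <- dy * !cache$colLeft
  dx <- array(0, d)
  dx[seq(1, d[1], 2), , , ] <- dm1 * cache$rowTop
  dx[seq(2, d[1], 2), , , ] <- dm1 * !cache$rowTop
  dx
}

# Global average pooling: (H, W, C, N) -> (C, N).
.gapForward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  matrix(colMeans(m), d[3], d[4])
}

.gapBackward <- function(dy, xDim) {
  # dy: (C, N) -> spread evenly over H x W
  sweepv <- rep(as.vector(dy), each = xDim[1] * xDim[2]) / (xDim[1] * xDim[2])
  array(sweepv, xDim)
}

.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# Channel mean and max maps: (H, W, C, N) -> two (H, W, 1, N) planes.
.channelPool <- function(x) {
  d <- dim(x)
  a3 <- array(x, c(d[1] * d[2], d[3], d[4]))
  avg <- array(0, c(d[1], d[2], 1, d[4]))
  mx <- array(0, c(d[1], d[2], 1, d[4]))
  accA <- a3[, 1, ]; accM <- a3[, 1, ]
  if (d[3] > 1) for (cc in 2:d[3]) {
    accA <- accA + a3[, cc, ]
    accM <- pmax(accM, a3[, cc, ])
  }
  avg[] <- accA / d[3]
  mx[] <- accM
  list(avg = avg, mx = mx)
}

# CBAM-style spatial attention: concat(channel mean, channel max) -> k x k
# conv (2 -> 1) -> logistic gate in (0,1) -> per-location multiplicative
# weight applied to every channel. Output shape equals input shape.
.saForward <- function(x, W, b) {
  d <- dim(x)
  cp <- .channelPool(x)
  s <- array(0, c(d[1], d[2], 2, d[4]))
  s[, , 1, ] <- cp$avg
  s[, , 2, ] <- cp$mx
  k <- dim(W)[1]
  cf <- .convForward(s, W, b, stride = 1L, pad = (k - 1L) %/% 2L)
  gate <- .sigmoid(cf$y)                       # (H, W, 1, N)
  gBig <- gate[, , rep(1, d[3]), , drop = FALSE]
  list(y = x * gBig, cache = list(x = x, s = s, conv = cf$cache,
                                  gate = gate, gBig = gBig, mx = cp$mx))
}

.saBackward <- function(dy, W, cache) {
  x <- cache$x
  d <- dim(x)
  dxDirect <- dy * cache$gBig
  dgate <- array(0, c(d[1], d[2], 1, d[4]))
  prod3 <- array(dy * x, c(d[1] * d[2], d[3], d[4]))
  acc <- prod3[, 1, ]
  if (d[3] > 1) for (cc in 2:d[3]) acc <- acc + prod3[, cc, ]
  dgate[] <- acc
  g <- cache$gate
  dg0 <- dgate * g * (1 - g)
  cb <- .convBackward(dg0, W, cache$conv)
  ds <- cb$dx                                  # (H, W, 2, N)
  davg <- ds[, , 1, , drop = FALSE]
  dmx <- ds[, , 2, , drop = FALSE]
  dx <- dxDirect + davg[, , rep(1, d[3]), , drop = FALSE] / d[3]
  # route the max-map gradient to the first channel attaining the max
  claimed <- array(FALSE, c(d[1], d[2], 1, d[4]))
  mx <- cache$mx
  for (cc in seq_len(d[3])) {
    sel <- (x[, , cc, , drop = FALSE] == mx) & !claimed
    dx[, , cc, ] <- dx[, , cc, ] + (dmx * sel)[, , 1, ]
    claimed <- claimed | sel
  }
  list(dx = dx, dW = cb$dW, db = cb$db)
}
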