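test_that("spatial attention preserves shape and bounds the output", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 5 * 3), c(8, 8, 5, 3))
  W <- array(rnorm(7 * 7 * 2 * 1, 0, 0.1), c(7, 7, 2, 1))
  sf <- ecganet:::.saForward(x, W, 0)
  expect_identical(dim(sf$y), dim(x))
  # the logistic gate lies in (0,1): |output| <= |input| elementwise
  expect_true(all(abs(sf$y) <= abs(x) + 1e-12))
  # zeros stay zeros (gate cannot change signs)
  x0 <- x; x0[1, 1, , ] <- 0
  sf0 <- ecganet:::.saForward(x0, W, 0)
  expect_true(all(sf0$y[1, 1, , ] == 0))
})

test_that("a saturated gate passes features through unchanged", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  W0 <- array(0, c(7, 7, 2, 1))
  sf <- ecganet:::.saForward(x, W0, 20)       # gate logit +20 everywhere
  expect_equal(sf$y, x, tolerance = 1e-6)
})

test_that("the structural audit finds 4 attention blocks between stages", {
  net <- buildNet(netConfig(), seed = 1)
  aud <- netAudit(net)
  expect_identical(attr(aud, "saCount"), 4L)
  # each attention block sits immediately after its stage, before the next
  saPos <- aud$position[aud$kind == "spatial_attention"]
  stPos <- aud$position[aud$kind == "residual_stage"]
  expect_identical(saPos, stPos + 1L)
  # the attention-free twin has none
  net0 <- buildNet(netConfig(saEnabled = FALSE), seed = 1)
  expect_identical(attr(netAudit(net0), "saCount"), 0L)
  # full-scale audit agrees structurally
  netF <- buildNet(netConfig(scale = "full", inputH = 224, inputW = 224),
                   seed = 1)
  expect_identical(attr(netAudit(netF), "saCount"), 4L)
})

test_that("forward output contracts hold", {
  net <- buildNet(netConfig(inputH = 32, inputW = 32), seed = 2)
  set.seed(43)
  x <- array(runif(32 * 32 * 1 * 5), c(32, 32, 1, 5))
  f1 <- netForward(net, x)
  expect_length(f1$z, 5L)
  expect_equal(f1$p, 1 / (1 + exp(-f1$z)), tolerance = 1e-12)
  expect_true(all(f1$p > 0 & f1$p < 1))
  # identical eval calls give identical outputs
  expect_identical(netForward(net, x)$z, f1$z)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 5, 2, 4)
  f2 <- netForward(net, x[, , , perm, drop = FALSE])
  expect_equal(f2$z, f1$z[perm], tolerance = 1e-12)
  # size mismatch is caught
  expect_error(netForward(net, array(0, c(16, 16, 1, 2))), "match")
})

test_that("saturating the gates reproduces the attention-free function", {
  cfg <- netConfig(inputH = 32, inputW = 32)
  net <- buildNet(cfg, seed = 5)
  net0 <- buildNet(netConfig(inputH = 32, inputW = 32, saEnabled = FALSE),
                   seed = 5)
  # share the backbone weights; only the attention parameters differ
  for (nm in names(net0@params)) net0@params[[nm]] <- net@params[[nm]]
  netSat <- saturateGates(net)
  set.seed(44)
  x <- array(runif(32 * 32 * 1 * 4), c(32, 32, 1, 4))
  zSat <- netForward(netSat, x)$z
  z0 <- netForward(net0, x)$z
  expect_equal(zSat, z0, tolerance = 1e-6)
  expect_error(saturateGates(net0), "without")
})

test_that("backpropagation matches finite differences through the network", {
  cfg <- netConfig(inputH = 32, inputW = 32)
  net <- buildNet(cfg, seed = 3)
  set.seed(45)
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  y <- c(1, 0, 1)
  lcfg <- brLossConfig()
  fw <- netForward(net, x, wantCache = TRUE)
  rc <- batchRecall(y, fw$p, lcfg)
  lg <- brLossGrad(y, fw$p, rc, lcfg)
  bw <- netBackward(net, fw$cache, dz = lg)
  lossAt <- function(params) {
    nt <- net; nt@params <- params
    brLoss(y, netForward(nt, x)$p, rc, lcfg)
  }
  eps <- 1e-4
  set.seed(46)
  for (nm in sample(names(net@params), 8)) {
    k <- sample(length(net@params[[nm]]), 1)
    p2 <- net@params; p2[[nm]][k] <- p2[[nm]][k] + eps
    p3 <- net@params; p3[[nm]][k] <- p3[[nm]][k] - eps
    fd <- (lossAt(p2) - lossAt(p3)) / (2 * eps)
    expect_equal(bw$grads[[nm]][k], fd, tolerance = 1e-4)
  }
})

test_that("grad-cam maps are normalized with an exact overlay rule", {
  net <- buildNet(netConfig(inputH = 32, inputW = 32), seed = 6)
  set.seed(47)
  img <- matrix(runif(32 * 32), 32, 32)
  for (stage in c(2L, 4L)) {
    cam <- gradCam(net, img, targetStage = stage)
    expect_gte(min(cam$values), 0)
    expect_lte(max(cam$values), 1)
    expect_gte(min(cam$map), 0)
    expect_lte(max(cam$map), 1)
    expect_identical(cam$overlay, cam$map > 0.4)
    expect_identical(dim(cam$map), dim(img))
  }
  expect_error(gradCam(net, img, targetStage = 5L), "1..4")
})

test_that("a constant-output model yields the flagged all-zero map", {
  net <- buildNet(netConfig(inputH = 32, inputW = 32), seed = 7)
  # zero the head: logit gradient reaches the stages, but the fc weights are
  # zero so the channel weights vanish and the rectified map is empty
  net@params$fc_W[] <- 0
  net@params$fc_b <- 0
  img <- matrix(runif(32 * 32), 32, 32)
  cam <- gradCam(net, img, targetStage = 4L)
  expect_true(cam$allZero)
  expect_true(all(cam$values == 0))
  expect_identical(sum(cam$overlay), 0L)
})

test_that("network configs validate their fields", {
  expect_error(netConfig(saKernel = 4), "odd")
  expect_error(netConfig(inputH = 30), "multiple")
  expect_error(netConfig(scale = "huge"), "tiny")
  expect_error(netConfig(threshold = 1.2), "threshold")
})
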