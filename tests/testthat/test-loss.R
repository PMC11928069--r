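test_that("batch recall counts classes at the threshold, ties positive", {
  r <- batchRecall(c(1, 1, 0, 0), c(0.9, 0.2, 0.1, 0.8))
  expect_equal(r$recall1, 0.5)
  expect_equal(r$recall0, 0.5)
  # all correct
  r2 <- batchRecall(c(1, 0), c(0.9, 0.1))
  expect_equal(r2$recall1, 1)
  expect_equal(r2$recall0, 1)
  # absent class convention: vacuous recall 1
  r3 <- batchRecall(c(0, 0), c(0.2, 0.3))
  expect_equal(r3$recall1, 1)
  expect_equal(r3$recall0, 1)
  # p equal to the threshold classifies as positive
  r4 <- batchRecall(c(1), c(0.5))
  expect_equal(r4$recall1, 1)
  expect_error(batchRecall(numeric(0), numeric(0)), "at least one")
})

test_that("the worked micro-batch reproduces the hand-derived loss", {
  # y = [1, 0], p = [0.5, 0.5]: both predicted positive, so recall1 = 1,
  # recall0 = 0; with zero weight floor w1 = 0, w0 = 1 and
  # L = (1/2) * (-log 0.5) = log(2)/2
  y <- c(1, 0); p <- c(0.5, 0.5)
  cfg <- brLossConfig(weightFloor = 0)
  rc <- batchRecall(y, p, cfg)
  expect_equal(rc$recall1, 1)
  expect_equal(rc$recall0, 0)
  expect_equal(brLoss(y, p, rc, cfg), log(2) / 2, tolerance = 1e-12)
  expect_equal(log(2) / 2, 0.346574, tolerance = 1e-5)
})

test_that("equal recalls reduce the loss to scaled cross-entropy", {
  set.seed(3)
  for (r in c(0, 0.3, 0.7, 1)) {
    y <- rep(c(1, 0), each = 8)
    p <- runif(16)
    cfg <- brLossConfig()
    rc <- list(recall1 = r, recall0 = r)
    expect_equal(brLoss(y, p, rc, cfg),
                 (1 - r + cfg$weightFloor) * bceLoss(y, p, cfg),
                 tolerance = 1e-12)
  }
  # weight floor 0 and both recalls 0: exactly standard cross-entropy
  y <- rep(c(1, 0), 4); p <- runif(8)
  cfg0 <- brLossConfig(weightFloor = 0)
  expect_equal(brLoss(y, p, list(recall1 = 0, recall0 = 0), cfg0),
               bceLoss(y, p, cfg0), tolerance = 1e-12)
})

test_that("the loss is non-negative, finite, and zero only when earned", {
  cfg <- brLossConfig()
  set.seed(4)
  for (i in 1:20) {
    y <- rbinom(12, 1, 0.5)
    p <- runif(12)
    L <- brLoss(y, p, cfg = cfg)
    expect_gte(L, 0)
    expect_true(is.finite(L))
  }
  # perfect confident predictions: zero loss (clamp makes logs finite)
  y <- c(1, 1, 0)
  expect_equal(brLoss(y, c(1, 1, 0), cfg = cfg), 0, tolerance = 1e-5)
  # extreme wrong predictions stay finite thanks to the clamp
  expect_true(is.finite(brLoss(c(1), c(0), cfg = cfg)))
})

test_that("analytic gradients match finite differences of the loss", {
  cfg <- brLossConfig()
  set.seed(6)
  for (i in 1:10) {
    y <- c(1, 0, rbinom(14, 1, 0.4))
    z <- rnorm(16)
    p <- 1 / (1 + exp(-z))
    rc <- batchRecall(y, p, cfg)           # held fixed, as in training
    g <- brLossGrad(y, p, rc, cfg)
    eps <- 1e-5
    for (k in sample(16, 4)) {
      zp <- z; zp[k] <- zp[k] + eps
      zm <- z; zm[k] <- zm[k] - eps
      fd <- (brLoss(y, 1 / (1 + exp(-zp)), rc, cfg) -
             brLoss(y, 1 / (1 + exp(-zm)), rc, cfg)) / (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-6)
    }
  }
})

test_that("gradient signs follow the class of the sample", {
  cfg <- brLossConfig()
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(10, 1, 0.5)
    p <- runif(10)
    g <- brLossGrad(y, p, cfg = cfg)
    expect_true(all(g[y == 1] <= 0))
    expect_true(all(g[y == 0] >= 0))
  }
  # converged positive sample: gradient tends to zero
  g <- brLossGrad(c(1), c(1 - 1e-9), list(recall1 = 1, recall0 = 1),
                  brLossConfig())
  expect_lt(abs(g), 1e-8)
})

test_that("falling recall monotonically amplifies its class gradients", {
  y <- c(1, 1, 0, 0); p <- c(0.6, 0.3, 0.2, 0.7)
  cfg <- brLossConfig()
  recalls <- seq(1, 0, by = -0.25)
  magPos <- vapply(recalls, function(r)
    max(abs(brLossGrad(y, p, list(recall1 = r, recall0 = 0.5), cfg)[y == 1])),
    numeric(1))
  expect_true(all(diff(magPos) >= 0))
  magNeg <- vapply(recalls, function(r)
    max(abs(brLossGrad(y, p, list(recall1 = 0.5, recall0 = r), cfg)[y == 0])),
    numeric(1))
  expect_true(all(diff(magNeg) >= 0))
})
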