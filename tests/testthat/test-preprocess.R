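test_that("binarization maps uniform pages to single-class masks", {
  cfg <- preprocessConfig()
  white <- matrix(255, 32, 40)
  black <- matrix(0, 32, 40)
  expect_false(any(binarizeInverted(white, cfg)))
  expect_true(all(binarizeInverted(black, cfg)))
  expect_identical(dim(binarizeInverted(white, cfg)), dim(white))
  expect_error(binarizeInverted(matrix(0, 0, 0), cfg), "empty")
  expect_error(preprocessConfig(threshold = 300), "threshold")
  expect_error(preprocessConfig(blurKernel = 4), "odd")
})

test_that("binarization keeps the trace and drops the grid on fixtures", {
  r <- deskReport()
  m <- binarizeInverted(r, preprocessConfig())
  sv <- maskSurvival(r, m)
  expect_gte(sv[["trace"]], 0.99)
  expect_lte(sv[["grid"]], 0.05)
})

test_that("otsu mode picks a cut separating trace from page", {
  r <- deskReport()
  m <- binarizeInverted(r, preprocessConfig(threshold = "otsu"))
  sv <- maskSurvival(r, m)
  expect_gte(sv[["trace"]], 0.95)
  expect_lte(sv[["grid"]], 0.30)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE   # diagonal chain
  m[7, 7] <- TRUE                                     # separate speck
  lab <- labelComponents(m)
  expect_identical(attr(lab, "n"), 2L)
  expect_identical(lab[2, 2], lab[3, 3])
  expect_identical(lab[3, 3], lab[4, 4])
  expect_false(lab[7, 7] == lab[2, 2])
})

test_that("component filtering removes specks and glyph-sized blocks only", {
  cfg <- preprocessConfig(minArea = 5, glyphMaxH = 4, glyphMaxW = 4)
  m <- matrix(FALSE, 40, 60)
  m[10:12, 5:55] <- TRUE                  # large stroke: kept
  specks <- cbind(c(2, 20, 30, 35, 38), c(2, 50, 10, 30, 58))
  m[specks] <- TRUE                       # five single-pixel specks: dropped
  out <- filterComponents(m, cfg)
  expect_identical(attr(labelComponents(m), "n"), 6L)
  expect_identical(attr(labelComponents(out), "n"), 1L)
  expect_true(all(out[10:12, 5:55]))
  # empty mask passes through
  e <- matrix(FALSE, 5, 5)
  expect_identical(filterComponents(e, cfg), e)
})

test_that("glyph blocks vanish while the trace survives, on fixtures", {
  r <- deskReport()
  cfg <- preprocessConfig()
  m1 <- binarizeInverted(r, cfg)
  m2 <- filterComponents(m1, cfg)
  gt <- groundTruthMasks(r)
  expect_lte(mean(m2[gt$glyph]), 0.05)              # >= 95% glyph removed
  survived <- m1 & gt$trace
  expect_gte(sum(m2 & survived) / sum(survived), 0.99)
})

test_that("opening removes isolated pixels, keeps 3x3 squares, is idempotent", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  expect_false(any(openMask(m)))
  sq <- matrix(FALSE, 10, 10); sq[4:6, 4:6] <- TRUE
  expect_identical(openMask(sq), sq)
  # idempotence and anti-extensivity on random masks
  set.seed(99)
  for (i in 1:10) {
    rm <- matrix(runif(30 * 30) < 0.4, 30, 30)
    o1 <- openMask(rm)
    expect_identical(openMask(o1), o1)
    expect_true(all(rm[o1]))          # output foreground subset of input
  }
})

test_that("filtering and opening never add foreground", {
  r <- deskReport()
  cfg <- preprocessConfig()
  m1 <- binarizeInverted(r, cfg)
  m2 <- filterComponents(m1, cfg)
  m3 <- openMask(m2)
  expect_true(all(m1[m2]))
  expect_true(all(m2[m3]))
})

test_that("equalize-and-rebinarize contracts hold", {
  cfg <- preprocessConfig()
  # high-constant plane -> all background
  allBg <- matrix(FALSE, 20, 20)
  expect_identical(equalizeRebinarize(allBg, cfg), allBg)
  # already-clean two-level input is a no-op under the default config
  m <- matrix(FALSE, 30, 30); m[10:12, 3:27] <- TRUE; m[20:25, 5:9] <- TRUE
  out <- equalizeRebinarize(m, cfg)
  expect_identical(out, m)
  expect_type(out, "logical")         # strictly two-valued
})

test_that("histogram equalization stretches to the full range", {
  g <- matrix(c(100, 100, 150, 150, 200, 200), 2, 3)
  eq <- histEqualize(g)
  expect_identical(min(eq), 0)        # darkest occupied level -> 0
  expect_identical(max(eq), 255)      # brightest -> 255
  expect_true(all(diff(sort(unique(as.vector(eq)))) > 0))
  # constant image -> background plane
  expect_true(all(histEqualize(matrix(7, 4, 4)) == 255))
})

test_that("the full chain is deterministic and faithful on fixtures", {
  r <- deskReport(seed = 43, st = 0.25, hr = 110, noise = 0.02, label = 1L)
  m1 <- preprocessReport(r)
  m2 <- preprocessReport(r)
  expect_identical(m1, m2)
  sv <- maskSurvival(r, m1)
  expect_gte(sv[["trace"]], 0.90)
  expect_lte(sv[["grid"]], 0.01)
  expect_lte(sv[["glyph"]], 0.05)
  # all-white page -> empty mask
  expect_false(any(preprocessReport(matrix(255, 64, 64))))
  expect_identical(dim(m1), dim(pixels(r)))
})
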