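# Synthetic 12-lead ECG report generation.
#
# The beat template is piecewise (Hann bumps for P/T, a triangular QRS, a flat
# ST plateau with short linear ramps) so that every landmark has an analytic
# pixel-level ground truth: inside the ST window the noiseless value is exactly
# the configured ST offset, and outside all waves the baseline is exactly 0 mV.

# Wave landmarks as fractions of the RR interval.
.BEAT <- list(
  pOn = 0.03, pOff = 0.13,
  qrsOn = 0.18, qrsPeak = 0.22, qrsOff = 0.26,
  stOn = 0.28, stOff = 0.40,
  tOn = 0.44, tOff = 0.62
)

.LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
            "V1", "V2", "V3", "V4", "V5", "V6")

#' Noiseless ECG template value at given times
#'
#' Evaluates the periodic P-QRS-T template of a \linkS4class{WaveformSpec} at
#' times \code{t}. Within the ST window of each beat the value equals the
#' spec's ST offset exactly; outside all waves, windows and transition ramps
#' the baseline is exactly 0 mV. Noise is never added here (see
#' \code{\link{sampleTrace}}).
#'
#' @param spec a \linkS4class{WaveformSpec}.
#' @param t numeric vector of times in seconds, each in [0, duration].
#' @return numeric vector of amplitudes in millivolts.
#' @examples
#' sp <- waveformSpec(heartRate = 60, stOffset = 0.2)
#' synthesizeBeat(sp, c(0, 0.22, 0.34))  # baseline, R peak, ST plateau
#' @export
synthesizeBeat <- function(spec, t) {
  stopifnot(is(spec, "WaveformSpec"))
  if (any(t < 0 | t > spec@duration))
    stop("t must lie within [0, duration_s]")
  period <- 60 / spec@heartRate
  ph <- (t %% period) / period  # phase in [0, 1)
  v <- numeric(length(ph))
  b <- .BEAT

  hann <- function(x, on, off) {
    # raised-cosine bump with compact support [on, off], peak 1 at midpoint
    w <- x >= on & x <= off
    out <- numeric(length(x))
    out[w] <- 0.5 - 0.5 * cos(2 * pi * (x[w] - on) / (off - on))
    out
  }

  v <- v + spec@pAmplitude * hann(ph, b$pOn, b$pOff)
  # triangular QRS
  up <- ph >= b$qrsOn & ph < b$qrsPeak
  dn <- ph >= b$qrsPeak & ph <= b$qrsOff
  v[up] <- v[up] + spec@qrsAmplitude * (ph[up] - b$qrsOn) / (b$qrsPeak - b$qrsOn)
  v[dn] <- v[dn] + spec@qrsAmplitude * (b$qrsOff - ph[dn]) / (b$qrsOff - b$qrsPeak)
  # ramp into the ST plateau, flat ST window, ramp out into the T wave
  r1 <- ph > b$qrsOff & ph < b$stOn
  v[r1] <- v[r1] + spec@stOffset * (ph[r1] - b$qrsOff) / (b$stOn - b$qrsOff)
  stw <- ph >= b$stOn & ph <= b$stOff
  v[stw] <- spec@stOffset
  r2 <- ph > b$stOff & ph < b$tOn
  v[r2] <- v[r2] + spec@stOffset * (b$tOn - ph[r2]) / (b$tOn - b$stOff)
  v <- v + spec@tAmplitude * hann(ph, b$tOn, b$tOff)
  v
}

#' Whether times fall inside an ST window
#'
#' @param spec a \linkS4class{WaveformSpec}.
#' @param t numeric vector of times in seconds.
#' @return logical vector, TRUE where \code{t} lies in the flat ST window of
#'   some beat.
#' @export
inStWindow <- function(spec, t) {
  period <- 60 / spec@heartRate
  ph <- (t %% period) / period
  ph >= .BEAT$stOn & ph <= .BEAT$stOff
}

#' Sample a noisy single-lead trace
#'
#' Evaluates the template on the spec's uniform sampling grid and adds
#' Gaussian noise drawn under the spec's seed, so the same spec always yields
#' a bit-identical trace. The caller's RNG state is left untouched.
#'
#' @param spec a \linkS4class{WaveformSpec}; its \code{seed} must be set when
#'   \code{noiseSd > 0}.
#' @param n optional number of samples; defaults to
#'   \code{duration * sampleRate + 1} uniform samples.
#' @return list with components \code{t} (times, s) and \code{mv} (values, mV).
#' @export
sampleTrace <- function(spec, n = NULL) {
  if (is.null(n)) n <- round(spec@duration * spec@sampleRate) + 1L
  t <- seq(0, spec@duration, length.out = n)
  mv <- synthesizeBeat(spec, t)
  if (spec@noiseSd > 0) {
    if (is.na(spec@seed))
      stop("a WaveformSpec with noise needs a seed for reproducibility")
    mv <- mv + withr::with_seed(spec@seed, stats::rnorm(n, 0, spec@noiseSd))
  }
  list(t = t, mv = mv)
}

# Solid glyph blocks standing in for a printed lead label. Each character is a
# filled h x ceil(0.7 h) block separated by one blank column, giving exact
# pixel oracles for the component-removal stage. Returns an index matrix
# (row, col) of glyph pixels relative to the panel's top-left corner.
.glyphPixels <- function(label, fontHeight) {
  nchar_ <- nchar(label)
  w <- max(2L, as.integer(ceiling(0.7 * fontHeight)))
  px <- NULL
  for (k in seq_len(nchar_)) {
    x0 <- (k - 1L) * (w + 2L)
    px <- rbind(px, cbind(
      rep(seq_len(fontHeight), times = w),
      rep(x0 + seq_len(w), each = fontHeight)
    ))
  }
  px
}

# Stamp a thickness x thickness square at each (y, x) center, clipped to
# [1, H] x [xlo, xhi]. Returns linear indices into an H x W matrix.
.stampStroke <- function(y, x, thickness, H, W, ylo, yhi, xlo, xhi) {
  h <- (thickness - 1L) %/% 2L
  off <- expand.grid(dy = -h:h, dx = -h:h)
  yy <- rep(y, times = nrow(off)) + rep(off$dy, each = length(y))
  xx <- rep(x, times = nrow(off)) + rep(off$dx, each = length(x))
  keep <- yy >= ylo & yy <= yhi & xx >= xlo & xx <= xhi
  unique((xx[keep] - 1L) * H + yy[keep])
}

#' Render a 12-lead ECG report raster
#'
#' Draws a white report page with fine/coarse background grid lines, one panel
#' per lead containing the rasterized trace, and a solid glyph block per lead
#' label, recording exact ground-truth masks (trace, grid, glyph, ST-window
#' pixels) during rasterization. Trace and glyphs are drawn at intensity 0,
#' the grid at the layout's grid intensity, on a 255 background; mask priority
#' is trace over glyph over grid.
#'
#' @param specs list of exactly 12 \linkS4class{WaveformSpec}, one per lead in
#'   the order I, II, III, aVR, aVL, aVF, V1-V6.
#' @param layout a \linkS4class{ReportLayout}.
#' @param seed integer seed used to derive per-panel noise seeds for specs
#'   whose own seed is NA.
#' @param label outcome label (0 or 1) stored on the report.
#' @return An \linkS4class{EcgReport}.
#' @examples
#' rep1 <- renderReport(replicate(12, waveformSpec(), simplify = FALSE),
#'                      deskLayout(), seed = 1)
#' @export
renderReport <- function(specs, layout, seed = 1L, label = 0L) {
  if (length(specs) != 12L)
    stop("exactly 12 waveform specs are required, one per lead panel")
  H <- layout@imageHeight; W <- layout@imageWidth
  pH <- H %/% layout@panelRows; pW <- W %/% layout@panelCols

  gridM <- matrix(FALSE, H, W); coarseM <- matrix(FALSE, H, W)
  gridM[seq(1L, H, by = layout@fineGrid), ] <- TRUE
  gridM[, seq(1L, W, by = layout@fineGrid)] <- TRUE
  coarseM[seq(1L, H, by = layout@coarseGrid), ] <- TRUE
  coarseM[, seq(1L, W, by = layout@coarseGrid)] <- TRUE

  traceM <- matrix(FALSE, H, W)
  glyphM <- matrix(FALSE, H, W)
  stM <- matrix(FALSE, H, W)

  for (p in seq_len(12L)) {
    sp <- specs[[p]]
    if (is.na(sp@seed))
      sp@seed <- as.integer((as.numeric(seed) * 131 + p) %% 2147483647)
    r <- (p - 1L) %/% layout@panelCols
    cc <- (p - 1L) %% layout@panelCols
    y0 <- r * pH + 1L; x0 <- cc * pW + 1L
    y1 <- y0 + pH - 1L; x1 <- x0 + pW - 1L
    yb <- y0 + round(layout@baselineFrac * pH)

    # dense enough that consecutive samples never move more than ~2 px, so
    # stamped squares of the stroke overlap along steep QRS edges
    nDense <- max(6L * pW, 4000L)
    tt <- seq(0, sp@duration, length.out = nDense)
    mv <- synthesizeBeat(sp, tt)
    if (sp@noiseSd > 0)
      mv <- mv + withr::with_seed(sp@seed, stats::rnorm(nDense, 0, sp@noiseSd))
    xs <- x0 + 1L + round((tt / sp@duration) * (pW - 4L))
    ys <- yb - round(mv * layout@mvPerPx)
    ys <- pmin(pmax(ys, y0 + 1L), y1 - 1L)

    idx <- .stampStroke(ys, xs, layout@traceThickness, H, W,
                        y0 + 1L, y1 - 1L, x0 + 1L, x1 - 1L)
    traceM[idx] <- TRUE
    inSt <- inStWindow(sp, tt)
    if (any(inSt)) {
      idxSt <- .stampStroke(ys[inSt], xs[inSt], layout@traceThickness, H, W,
                            y0 + 1L, y1 - 1L, x0 + 1L, x1 - 1L)
      stM[idxSt] <- TRUE
    }

    gp <- .glyphPixels(.LEADS[p], layout@labelFontHeight)
    gy <- y0 + 1L + gp[, 1L]; gx <- x0 + 1L + gp[, 2L]
    keep <- gy <= y1 & gx <= x1
    glyphM[(gx[keep] - 1L) * H + gy[keep]] <- TRUE
  }

  # compose raster; priority trace > glyph > grid > page
  img <- matrix(255, H, W)
  img[gridM] <- layout@gridIntensity
  img[coarseM] <- max(0, layout@gridIntensity - 40)
  img[glyphM] <- 0
  img[traceM] <- 0

  gridAll <- (gridM | coarseM) & !traceM & !glyphM
  glyphM <- glyphM & !traceM
  stM <- stM & traceM

  new("EcgReport",
    pixels = img, label = as.integer(label), specs = specs, layout = layout,
    masks = list(trace = traceM, grid = gridAll, glyph = glyphM, st = stM)
  )
}

#' Case/control generating distributions for synthetic datasets
#'
#' Uniform ranges for the two class-signal parameters. The defaults emulate
#' the qualitative pre-arrest picture with disjoint class supports — cases
#' carry an elevated ST segment (0.2-0.4 mV versus -0.05 to 0.05 mV in
#' controls) and tachycardia (100-140 bpm versus 60-90 bpm) — giving the
#' strongly separable regime the desk-scale learning checks assume.
#' Overlapping ranges can be passed for harder tasks.
#'
#' @param caseSt,controlSt ST-offset ranges (mV) for cases and controls.
#' @param caseHr,controlHr heart-rate ranges (bpm).
#' @param qrsRange QRS amplitude jitter range (mV), shared by both classes.
#' @param noiseSd trace noise SD (mV), shared by both classes.
#' @return A named list of distribution parameters.
#' @export
ecgEffect <- function(caseSt = c(0.2, 0.4), controlSt = c(-0.05, 0.05),
                      caseHr = c(100, 140), controlHr = c(60, 90),
                      qrsRange = c(0.8, 1.1), noiseSd = 0.02) {
  list(caseSt = caseSt, controlSt = controlSt, caseHr = caseHr,
       controlHr = controlHr, qrsRange = qrsRange, noiseSd = noiseSd)
}

#' Generate a labeled synthetic ECG report dataset
#'
#' Draws per-image heart rate, ST offset and QRS amplitude from the class
#' distributions in \code{effect}, renders each report, and returns the
#' images together with a full generation manifest (label, parameters and
#' per-image seed) sufficient to regenerate every image bit-identically.
#' The positive proportion is achieved exactly, not in expectation, and the
#' report order is shuffled under the same seed.
#'
#' @param nPos,nNeg numbers of case (label 1) and control (label 0) images;
#'   the total must be at least 1.
#' @param effect distribution parameters, see \code{\link{ecgEffect}}.
#' @param layout a \linkS4class{ReportLayout}.
#' @param seed integer master seed.
#' @return An \linkS4class{EcgDataset}. If the case and control distributions
#'   are identical the manifest carries attribute \code{degenerate = TRUE}.
#' @examples
#' ds <- generateDataset(2, 3, layout = deskLayout(), seed = 7)
#' labels(ds)
#' @export
generateDataset <- function(nPos, nNeg, effect = ecgEffect(),
                            layout = deskLayout(), seed = 1L) {
  if (nPos < 0 || nNeg < 0 || nPos + nNeg < 1)
    stop("need nPos >= 0, nNeg >= 0 and at least one image")
  n <- nPos + nNeg
  degenerate <- identical(effect$caseSt, effect$controlSt) &&
    identical(effect$caseHr, effect$controlHr)
  if (degenerate)
    message("case and control distributions are identical; dataset is flagged degenerate")

  lab <- c(rep(1L, nPos), rep(0L, nNeg))
  params <- withr::with_seed(seed, {
    hr <- ifelse(lab == 1L,
      stats::runif(n, effect$caseHr[1], effect$caseHr[2]),
      stats::runif(n, effect$controlHr[1], effect$controlHr[2]))
    st <- ifelse(lab == 1L,
      stats::runif(n, effect$caseSt[1], effect$caseSt[2]),
      stats::runif(n, effect$controlSt[1], effect$controlSt[2]))
    qrs <- stats::runif(n, effect$qrsRange[1], effect$qrsRange[2])
    seeds <- sample.int(2147483646L, n)
    ord <- sample.int(n, n)
    list(hr = hr, st = st, qrs = qrs, seeds = seeds, ord = ord)
  })
  ord <- params$ord
  reports <- vector("list", n)
  for (j in seq_len(n)) {
    i <- ord[j]
    specs <- lapply(seq_len(12L), function(p) {
      waveformSpec(
        heartRate = params$hr[i], stOffset = params$st[i],
        qrsAmplitude = params$qrs[i], noiseSd = effect$noiseSd,
        seed = (as.numeric(params$seeds[i]) * 31 + p) %% 2147483647
      )
    })
    reports[[j]] <- renderReport(specs, layout, seed = params$seeds[i],
                                 label = lab[i])
  }
  man <- data.frame(
    id = sprintf("ecg%04d", seq_len(n)),
    label = lab[ord],
    heartRate = params$hr[ord],
    stOffset = params$st[ord],
    qrsAmplitude = params$qrs[ord],
    noiseSd = effect$noiseSd,
    seed = params$seeds[ord]
  )
  attr(man, "degenerate") <- degenerate
  new("EcgDataset", reports = reports, manifest = man)
}
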