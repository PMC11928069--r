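# Shared fixtures, memoized so expensive renders happen once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# One noiseless desk-size report with known masks.
deskReport <- function(seed = 42, st = 0, hr = 75, noise = 0, label = 0L) {
  memo(paste("rep", seed, st, hr, noise, label), {
    specs <- lapply(1:12, function(p)
      waveformSpec(heartRate = hr, stOffset = st, noiseSd = noise,
                   seed = seed * 100 + p))
    renderReport(specs, deskLayout(), seed = seed, label = label)
  })
}

# Small balanced desk dataset.
deskDataset <- function(nPos = 6, nNeg = 6, seed = 7) {
  memo(paste("ds", nPos, nNeg, seed),
       generateDataset(nPos, nNeg, layout = deskLayout(), seed = seed))
}

# Independent all-pairs AUROC oracle (ties half credit).
aurocBrute <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Independent AUPRC oracle: explicit precision/recall at every unique
# threshold, step summation, no interpolation.
auprcBrute <- function(y, p) {
  thr <- sort(unique(p), decreasing = TRUE)
  area <- 0; rPrev <- 0
  nPos <- sum(y == 1)
  for (t in thr) {
    tp <- 0; fp <- 0
    for (i in seq_along(p)) {
      if (p[i] >= t) { if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1 }
    }
    rec <- tp / nPos; prec <- tp / (tp + fp)
    area <- area + (rec - rPrev) * prec
    rPrev <- rec
  }
  area
}
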