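# Image-cleanup chain: blur/threshold binarization, connected-component label
# removal, 3x3 morphological opening, and equalize-and-rebinarize.
#
# Internal convention throughout: a binary mask is a logical matrix with
# foreground = TRUE = waveform pixels. The printed-report encoding (trace
# black on white) is an I/O representation handled at the boundary by
# maskToImage()/imageToGray().

#' Configuration for the ECG image-cleanup chain
#'
#' All stage parameters of \code{\link{preprocessReport}}. Defaults are
#' calibrated on the in-package synthetic report fixtures and exposed in full;
#' thresholds operate on the 0-255 intensity scale.
#'
#' @slot blurKernel odd Gaussian kernel size (px) for the initial blur; 1
#'   disables blurring.
#' @slot blurSigma Gaussian sigma (px) for the initial blur.
#' @slot threshold intensity cut for the initial binarization: blurred pixels
#'   strictly below it become foreground. Ignored when
#'   \code{thresholdMode = "otsu"}.
#' @slot thresholdMode "fixed" or "otsu" (automatic threshold on the blurred
#'   image).
#' @slot minArea connected components with fewer foreground pixels than this
#'   are removed.
#' @slot glyphMaxH,glyphMaxW components whose bounding box fits within this
#'   height and width (the text-glyph size rule) are removed.
#' @slot finalBlurKernel,finalBlurSigma Gaussian blur of the final
#'   equalize-and-rebinarize stage; the default kernel of 1 disables it, since
#'   the opened mask of a noiseless rendering is already clean and any blur
#'   would dilate the stroke by one pixel ring.
#' @slot finalThreshold intensity cut applied after histogram equalization.
#'
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(
    blurKernel = "integer", blurSigma = "numeric",
    threshold = "numeric", thresholdMode = "character",
    minArea = "integer", glyphMaxH = "integer", glyphMaxW = "integer",
    finalBlurKernel = "integer", finalBlurSigma = "numeric",
    finalThreshold = "numeric"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@blurKernel < 1L || object@blurKernel %% 2L == 0L)
    msg <- c(msg, "blurKernel must be odd and >= 1")
  if (object@finalBlurKernel < 1L || object@finalBlurKernel %% 2L == 0L)
    msg <- c(msg, "finalBlurKernel must be odd and >= 1")
  if (!object@thresholdMode %in% c("fixed", "otsu"))
    msg <- c(msg, "thresholdMode must be 'fixed' or 'otsu'")
  if (object@thresholdMode == "fixed" &&
      (object@threshold < 0 || object@threshold > 255))
    msg <- c(msg, "threshold must lie in [0, 255]")
  if (object@finalThreshold < 0 || object@finalThreshold > 255)
    msg <- c(msg, "finalThreshold must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct a preprocessing configuration
#'
#' @param blurKernel,blurSigma initial Gaussian blur (odd kernel size in px,
#'   sigma in px).
#' @param threshold initial binarization cut on the 0-255 scale, or the string
#'   "otsu" for an automatic threshold.
#' @param minArea minimum component area (px^2) kept.
#' @param glyphMaxH,glyphMaxW bounding-box size rule for text-like components.
#' @param finalBlurKernel,finalBlurSigma blur of the final stage (kernel 1 =
#'   off).
#' @param finalThreshold cut applied after histogram equalization.
#' @return A \linkS4class{PreprocessConfig}.
#' @examples
#' preprocessConfig()
#' preprocessConfig(threshold = "otsu")
#' @export
preprocessConfig <- function(blurKernel = 3, blurSigma = 0.5, threshold = 128,
                             minArea = 30, glyphMaxH = 10, glyphMaxW = 10,
                             finalBlurKernel = 1, finalBlurSigma = 0,
                             finalThreshold = 128) {
  mode <- if (identical(threshold, "otsu")) "otsu" else "fixed"
  new("PreprocessConfig",
    blurKernel = as.integer(blurKernel), blurSigma = blurSigma,
    threshold = if (mode == "otsu") NA_real_ else threshold,
    thresholdMode = mode,
    minArea = as.integer(minArea),
    glyphMaxH = as.integer(glyphMaxH), glyphMaxW = as.integer(glyphMaxW),
    finalBlurKernel = as.integer(finalBlurKernel),
    finalBlurSigma = finalBlurSigma, finalThreshold = finalThreshold
  )
}

setMethod("show", "PreprocessConfig", function(object) {
  thr <- if (object@thresholdMode == "otsu") "otsu" else
    format(object@threshold)
  cat(sprintf(
    "PreprocessConfig: blur %dpx/sigma %g, threshold %s, minArea %d, glyph <= %dx%d, final blur %dpx, final threshold %g\n",
    object@blurKernel, object@blurSigma, thr, object@minArea,
    object@glyphMaxH, object@glyphMaxW, object@finalBlurKernel,
    object@finalThreshold
  ))
})

# -- helpers -----------------------------------------------------------------

.toGray <- function(image) {
  if (is(image, "EcgReport")) image <- image@pixels
  d <- dim(image)
  if (length(d) == 3L) image <- apply(image, c(1L, 2L), mean)
  if (!is.matrix(image) || nrow(image) == 0L || ncol(image) == 0L)
    stop("image must be a non-empty matrix (or an EcgReport)")
  image
}

# Separable Gaussian convolution with replicate boundary. The 2-d Gaussian
# kernel factorizes exactly, so this equals convolution with the full
# kernel x kernel Gaussian brush at a fraction of the cost.
.gaussBlur <- function(g, kernel, sigma) {
  if (kernel <= 1L || sigma <= 0) return(g)
  h <- (kernel - 1L) %/% 2L
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- w / sum(w)
  H <- nrow(g); W <- ncol(g)
  tmp <- matrix(0, H, W)
  for (s in -h:h)
    tmp <- tmp + w[s + h + 1L] * g[pmin(pmax(seq_len(H) + s, 1L), H), ,
                                   drop = FALSE]
  out <- matrix(0, H, W)
  for (s in -h:h)
    out <- out + w[s + h + 1L] * tmp[, pmin(pmax(seq_len(W) + s, 1L), W),
                                     drop = FALSE]
  out
}

#' Convert between binary masks and printed-report intensity images
#'
#' \code{maskToImage} renders a foreground=TRUE mask back to the printed
#' convention (trace 0, background 255); \code{imageToGray} reduces a raster
#' or \linkS4class{EcgReport} to a single 0-255 intensity plane.
#'
#' @param mask logical matrix, foreground = TRUE.
#' @param image numeric matrix, 3-plane array, or \linkS4class{EcgReport}.
#' @return numeric matrix of 0-255 intensities.
#' @export
maskToImage <- function(mask) {
  out <- matrix(255, nrow(mask), ncol(mask))
  out[mask] <- 0
  out
}

#' @rdname maskToImage
#' @export
imageToGray <- function(image) .toGray(image)

# -- stage 1: blur + inverted threshold --------------------------------------

#' Binarize an ECG report image (dark trace becomes foreground)
#'
#' Applies a Gaussian blur, then thresholds: pixels with blurred intensity
#' strictly below the cut (the dark trace and labels) become foreground,
#' everything at or above it (white page, faint grid lines) becomes
#' background. This is the inverted-binary step that removes thin grid lines.
#'
#' @param image raster (0-255 matrix, 3-plane array) or
#'   \linkS4class{EcgReport}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return logical matrix, foreground = TRUE.
#' @examples
#' r <- renderReport(replicate(12, waveformSpec(), simplify = FALSE),
#'                   deskLayout(), seed = 1)
#' m <- binarizeInverted(r, preprocessConfig())
#' @export
binarizeInverted <- function(image, cfg = preprocessConfig()) {
  g <- .toGray(image)
  b <- .gaussBlur(g, cfg@blurKernel, cfg@blurSigma)
  thr <- if (cfg@thresholdMode == "otsu") {
    EBImage::otsu(EBImage::Image(b / 255), range = c(0, 1)) * 255
  } else cfg@threshold
  b < thr
}

# -- stage 2: connected-component filtering ----------------------------------

#' Label 8-connected foreground components
#'
#' Components are maximal sets of foreground pixels connected through their 8
#' neighbours. Implemented as a 4-connected labelling pass followed by a
#' union-find merge of labels that touch diagonally.
#'
#' @param mask logical matrix, foreground = TRUE.
#' @return integer matrix of component labels (0 = background), with
#'   attribute \code{n} giving the number of components.
#' @export
labelComponents <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  if (nl > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    # diagonal neighbour pairs with different non-zero labels
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right
    a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(nl)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nl), find, integer(1))
      remap <- match(root, sort(unique(root)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      nl <- max(lab)
    }
  }
  attr(lab, "n") <- nl
  lab
}

#' Remove small and text-like connected components
#'
#' Deletes 8-connected foreground components whose area falls below
#' \code{minArea}, or whose bounding box fits within the glyph size rule
#' (height <= \code{glyphMaxH} and width <= \code{glyphMaxW}); this is what
#' removes printed lead labels and specks. All surviving components are
#' preserved pixel-exactly, so the output foreground is a subset of the input
#' foreground.
#'
#' @param mask logical matrix, foreground = TRUE.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return logical matrix, foreground = TRUE.
#' @export
filterComponents <- function(mask, cfg = preprocessConfig()) {
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask)
  nl <- attr(lab, "n")
  fg <- which(lab > 0L)
  lv <- lab[fg]
  ri <- ((fg - 1L) %% nrow(mask)) + 1L
  ci <- ((fg - 1L) %/% nrow(mask)) + 1L
  area <- tabulate(lv, nbins = nl)
  rmin <- stats::aggregate(ri, list(lv), min)$x
  rmax <- stats::aggregate(ri, list(lv), max)$x
  cmin <- stats::aggregate(ci, list(lv), min)$x
  cmax <- stats::aggregate(ci, list(lv), max)$x
  bbH <- rmax - rmin + 1L
  bbW <- cmax - cmin + 1L
  drop <- area < cfg@minArea | (bbH <= cfg@glyphMaxH & bbW <= cfg@glyphMaxW)
  out <- mask
  out[fg[drop[lv]]] <- FALSE
  out
}

# -- stage 3: morphological opening ------------------------------------------

#' Morphological opening with a 3 x 3 structuring element
#'
#' Erosion followed by dilation with the fixed 3 x 3 all-ones element,
#' smoothing the trace and deleting structures smaller than the element.
#' Opening is anti-extensive (never adds foreground) and idempotent.
#'
#' @param mask logical matrix, foreground = TRUE.
#' @return logical matrix, foreground = TRUE.
#' @export
openMask <- function(mask) {
  kern <- EBImage::makeBrush(3, shape = "box")
  as.matrix(EBImage::opening(mask * 1, kern)) > 0.5
}

# -- stage 4: equalize and rebinarize ----------------------------------------

#' Histogram equalization on the 0-255 scale
#'
#' Classic cdf-based equalization with the min-bin normalization
#' \eqn{v' = round(255 (F(v) - F_{min}) / (1 - F_{min}))}, where F is the
#' intensity cdf and \eqn{F_{min}} its value at the lowest occupied bin, so
#' the darkest occupied level maps to 0 and the brightest to 255. A constant
#' image maps to the all-255 (background) plane by convention.
#'
#' @param g numeric matrix of 0-255 intensities.
#' @return numeric matrix of equalized 0-255 intensities.
#' @export
histEqualize <- function(g) {
  v <- floor(pmin(pmax(g, 0), 255))
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / sum(h)
  cdfmin <- cdf[which(h > 0L)[1L]]
  if (cdfmin >= 1) return(matrix(255, nrow(g), ncol(g)))
  map <- pmax(round(255 * (cdf - cdfmin) / (1 - cdfmin)), 0)
  matrix(map[v + 1L], nrow(g), ncol(g))
}

#' Equalize and rebinarize an opened mask
#'
#' Final cleanup stage: the opened mask is rendered back to a 0-255 grayscale
#' plane (trace 0, background 255), optionally blurred, histogram-equalized to
#' stretch the contrast between the trace and any residual background, and
#' thresholded again at \code{finalThreshold}. The output is strictly
#' two-valued.
#'
#' @param mask logical matrix, foreground = TRUE.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return logical matrix, foreground = TRUE.
#' @export
equalizeRebinarize <- function(mask, cfg = preprocessConfig()) {
  g <- maskToImage(mask)
  g <- .gaussBlur(g, cfg@finalBlurKernel, cfg@finalBlurSigma)
  eq <- histEqualize(g)
  eq < cfg@finalThreshold
}

# -- full chain --------------------------------------------------------------

#' Full ECG report cleanup chain
#'
#' Composition, in order: \code{\link{binarizeInverted}} (blur + inverted
#' threshold, removes the grid), \code{\link{filterComponents}} (removes lead
#' labels and specks), \code{\link{openMask}} (3 x 3 opening), and
#' \code{\link{equalizeRebinarize}}. Deterministic; every stage preserves the
#' raster dimensions and the foreground=TRUE convention.
#'
#' @param image raster or \linkS4class{EcgReport}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return logical matrix, foreground = TRUE = waveform pixels.
#' @examples
#' r <- renderReport(replicate(12, waveformSpec(), simplify = FALSE),
#'                   deskLayout(), seed = 1)
#' m <- preprocessReport(r)
#' mean(m[groundTruthMasks(r)$trace])   # trace survival
#' @export
preprocessReport <- function(image, cfg = preprocessConfig()) {
  m <- binarizeInverted(image, cfg)
  m <- filterComponents(m, cfg)
  m <- openMask(m)
  equalizeRebinarize(m, cfg)
}

#' Survival rates of ground-truth pixel classes after preprocessing
#'
#' Convenience audit used by the tests and the acceptance script: given a
#' generated report (whose ground-truth masks are known) and a processed
#' mask, returns the fraction of trace, grid and glyph pixels that remain
#' foreground.
#'
#' @param report an \linkS4class{EcgReport} with ground-truth masks.
#' @param mask a processed logical mask of the same dimensions.
#' @return named numeric vector with elements \code{trace}, \code{grid},
#'   \code{glyph}.
#' @export
maskSurvival <- function(report, mask) {
  gt <- report@masks
  if (!length(gt)) stop("report carries no ground-truth masks")
  c(trace = mean(mask[gt$trace]),
    grid = mean(mask[gt$grid]),
    glyph = mean(mask[gt$glyph]))
}
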