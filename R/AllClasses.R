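#' @import methods
NULL

#' Waveform specification for one synthetic ECG lead
#'
#' Describes a 10-second single-lead trace as a periodic P-QRS-T template with
#' an explicit flat ST window. The ST-segment baseline shift
#' (\code{stOffset}, mV) and the heart rate (\code{heartRate}, beats/min)
#' carry the class signal in synthetic case/control datasets: ST deviation is
#' the classic ischemia marker and tachycardia a common pre-arrest finding.
#'
#' @slot heartRate beats per minute, in [20, 300].
#' @slot stOffset signed ST-segment baseline shift in millivolts.
#' @slot qrsAmplitude R-wave peak amplitude in millivolts.
#' @slot pAmplitude,tAmplitude P- and T-wave peak amplitudes in millivolts.
#' @slot noiseSd standard deviation of additive Gaussian trace noise (mV).
#' @slot duration trace duration in seconds (default 10).
#' @slot sampleRate sampling rate in Hz.
#' @slot seed integer seed making the sampled noise reproducible; NA means
#'   "derive from the rendering seed".
#'
#' @exportClass WaveformSpec
setClass("WaveformSpec",
  representation(
    heartRate = "numeric", stOffset = "numeric", qrsAmplitude = "numeric",
    pAmplitude = "numeric", tAmplitude = "numeric", noiseSd = "numeric",
    duration = "numeric", sampleRate = "numeric", seed = "integer"
  )
)

setValidity("WaveformSpec", function(object) {
  msg <- character()
  if (object@heartRate < 20 || object@heartRate > 300)
    msg <- c(msg, "heartRate must lie in [20, 300] bpm")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a WaveformSpec
#'
#' @param heartRate heart rate in beats/min.
#' @param stOffset ST-segment offset in mV.
#' @param qrsAmplitude,pAmplitude,tAmplitude wave amplitudes in mV.
#' @param noiseSd additive Gaussian noise SD in mV.
#' @param duration trace duration in seconds.
#' @param sampleRate sampling rate in Hz.
#' @param seed integer noise seed (NA to derive from the render seed).
#' @return A \linkS4class{WaveformSpec}.
#' @examples
#' waveformSpec(heartRate = 72, stOffset = 0.2)
#' @export
waveformSpec <- function(heartRate = 75, stOffset = 0, qrsAmplitude = 1,
                         pAmplitude = 0.12, tAmplitude = 0.25, noiseSd = 0,
                         duration = 10, sampleRate = 250, seed = NA_integer_) {
  new("WaveformSpec",
    heartRate = heartRate, stOffset = stOffset, qrsAmplitude = qrsAmplitude,
    pAmplitude = pAmplitude, tAmplitude = tAmplitude, noiseSd = noiseSd,
    duration = duration, sampleRate = sampleRate, seed = as.integer(seed)
  )
}

setMethod("show", "WaveformSpec", function(object) {
  cat(sprintf(
    "WaveformSpec: %g bpm, ST %+.3f mV, QRS %.2f mV, noise %.3f mV, %gs @ %g Hz\n",
    object@heartRate, object@stOffset, object@qrsAmplitude, object@noiseSd,
    object@duration, object@sampleRate
  ))
})

#' Page layout for a rendered 12-lead ECG report
#'
#' Geometry of the synthetic report raster: page size, the 3 x 4 arrangement of
#' lead panels, fine/coarse background grid spacing, grid and trace rendering
#' parameters, and the millivolt-to-pixel scale. Intensities follow the printed
#' report convention: white page (255), light grid, dark trace/labels (0).
#'
#' @slot imageWidth,imageHeight page size in pixels.
#' @slot panelRows,panelCols arrangement of the 12 lead panels.
#' @slot fineGrid,coarseGrid grid line spacings in pixels; coarse must be an
#'   integer multiple of fine.
#' @slot gridIntensity intensity (0-255) of fine grid lines; coarse lines are
#'   drawn slightly darker but always lighter than the trace.
#' @slot traceThickness odd stroke thickness of the waveform in pixels.
#' @slot labelFontHeight height in pixels of the solid glyph blocks standing in
#'   for printed lead labels.
#' @slot mvPerPx vertical scale, pixels per millivolt.
#' @slot baselineFrac fraction of panel height at which the isoelectric
#'   baseline sits.
#'
#' @exportClass ReportLayout
setClass("ReportLayout",
  representation(
    imageWidth = "integer", imageHeight = "integer",
    panelRows = "integer", panelCols = "integer",
    fineGrid = "integer", coarseGrid = "integer",
    gridIntensity = "numeric", traceThickness = "integer",
    labelFontHeight = "integer", mvPerPx = "numeric", baselineFrac = "numeric"
  )
)

setValidity("ReportLayout", function(object) {
  msg <- character()
  if (object@coarseGrid %% object@fineGrid != 0)
    msg <- c(msg, "coarseGrid must be an integer multiple of fineGrid")
  if (object@panelRows * object@panelCols != 12L)
    msg <- c(msg, "panel grid must hold exactly 12 lead panels")
  pw <- object@imageWidth %/% object@panelCols
  ph <- object@imageHeight %/% object@panelRows
  if (pw < 16L || ph < 16L)
    msg <- c(msg, "panels do not fit inside the image bounds (min 16x16 px each)")
  if (object@traceThickness < 1L || object@traceThickness %% 2L == 0L)
    msg <- c(msg, "traceThickness must be odd and >= 1")
  if (object@gridIntensity < 0 || object@gridIntensity > 255)
    msg <- c(msg, "gridIntensity must lie in [0, 255]")
  if (object@labelFontHeight + 4L > ph)
    msg <- c(msg, "label glyphs do not fit inside a panel")
  if (length(msg)) msg else TRUE
})

#' Construct a report layout
#'
#' @param imageWidth,imageHeight page size in pixels.
#' @param panelRows,panelCols lead panel arrangement (must hold 12 panels).
#' @param fineGrid,coarseGrid grid spacings in pixels.
#' @param gridIntensity fine grid line intensity (0-255).
#' @param traceThickness odd trace stroke width in pixels.
#' @param labelFontHeight lead-label glyph height in pixels.
#' @param mvPerPx vertical scale in pixels per millivolt.
#' @param baselineFrac baseline position as a fraction of panel height.
#' @return A \linkS4class{ReportLayout}.
#' @examples
#' reportLayout()        # full-page 1024 x 768 default
#' deskLayout()          # small 256 x 192 preset used throughout the tests
#' @export
reportLayout <- function(imageWidth = 1024, imageHeight = 768,
                         panelRows = 3, panelCols = 4,
                         fineGrid = 16, coarseGrid = 80,
                         gridIntensity = 200, traceThickness = 3,
                         labelFontHeight = 12, mvPerPx = 60,
                         baselineFrac = 0.62) {
  new("ReportLayout",
    imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight),
    panelRows = as.integer(panelRows), panelCols = as.integer(panelCols),
    fineGrid = as.integer(fineGrid), coarseGrid = as.integer(coarseGrid),
    gridIntensity = gridIntensity, traceThickness = as.integer(traceThickness),
    labelFontHeight = as.integer(labelFontHeight), mvPerPx = mvPerPx,
    baselineFrac = baselineFrac
  )
}

#' @describeIn reportLayout Small 256 x 192 page preset sized so that every
#'   test and example runs in seconds on one CPU.
#' @export
deskLayout <- function() {
  reportLayout(
    imageWidth = 256, imageHeight = 192, fineGrid = 8, coarseGrid = 40,
    gridIntensity = 200, traceThickness = 3, labelFontHeight = 6, mvPerPx = 20
  )
}

setMethod("show", "ReportLayout", function(object) {
  cat(sprintf(
    "ReportLayout: %dx%d px, %dx%d panels, grid %d/%d px @ %g, trace %d px, %g px/mV\n",
    object@imageWidth, object@imageHeight, object@panelRows, object@panelCols,
    object@fineGrid, object@coarseGrid, object@gridIntensity,
    object@traceThickness, object@mvPerPx
  ))
})

#' A labeled synthetic ECG report image
#'
#' One rendered report page plus its binary outcome label and, when generated
#' in-package, exact ground-truth pixel masks recorded during rasterization:
#' \code{trace} (waveform stroke pixels), \code{grid} (background grid),
#' \code{glyph} (lead-label blocks) and \code{st} (the subset of trace pixels
#' drawn inside an ST window). Masks are pairwise disjoint after priority
#' resolution (trace over glyph over grid; \code{st} is a subset of
#' \code{trace}). Reports read back from disk carry empty masks.
#'
#' @slot pixels numeric matrix (rows = image height) of 0-255 intensities.
#' @slot label integer outcome, 1 = cardiac-arrest case, 0 = control.
#' @slot specs list of 12 \linkS4class{WaveformSpec}, one per lead panel.
#' @slot layout the \linkS4class{ReportLayout} used.
#' @slot masks named list of logical matrices (possibly empty).
#'
#' @exportClass EcgReport
setClass("EcgReport",
  representation(
    pixels = "matrix", label = "integer", specs = "list",
    layout = "ReportLayout", masks = "list"
  )
)

setValidity("EcgReport", function(object) {
  msg <- character()
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  if (nrow(object@pixels) != object@layout@imageHeight ||
      ncol(object@pixels) != object@layout@imageWidth)
    msg <- c(msg, "pixel raster does not match the layout dimensions")
  if (length(object@masks)) {
    dm <- vapply(object@masks, function(m) identical(dim(m), dim(object@pixels)),
                 logical(1))
    if (!all(dm)) msg <- c(msg, "masks must match the raster dimensions")
    tg <- c("trace", "grid", "glyph")
    if (all(tg %in% names(object@masks))) {
      ov <- (object@masks$trace & object@masks$grid) |
            (object@masks$trace & object@masks$glyph) |
            (object@masks$grid & object@masks$glyph)
      if (any(ov)) msg <- c(msg, "trace/grid/glyph masks must be pairwise disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EcgReport", function(object) {
  cat(sprintf(
    "EcgReport: %dx%d px, label %d, %d ground-truth masks (%s)\n",
    nrow(object@pixels), ncol(object@pixels), object@label,
    length(object@masks), paste(names(object@masks), collapse = ", ")
  ))
})

#' A set of labeled ECG report images
#'
#' Holds the rendered \linkS4class{EcgReport} objects together with the
#' generation manifest: one row per image recording label, heart rate,
#' ST offset, QRS amplitude, noise level and the per-image seed, which is
#' sufficient to regenerate the image bit-identically.
#'
#' @slot reports list of \linkS4class{EcgReport}.
#' @slot manifest data.frame with one row per report.
#'
#' @exportClass EcgDataset
setClass("EcgDataset",
  representation(reports = "list", manifest = "data.frame")
)

setValidity("EcgDataset", function(object) {
  if (length(object@reports) != nrow(object@manifest))
    return("manifest must have one row per report")
  TRUE
})

setMethod("show", "EcgDataset", function(object) {
  lb <- labels(object)
  cat(sprintf(
    "EcgDataset: %d reports (%d positive, %d negative)\n",
    length(object@reports), sum(lb == 1L), sum(lb == 0L)
  ))
})

#' @describeIn EcgDataset number of reports.
#' @param x an EcgDataset.
#' @export
setMethod("length", "EcgDataset", function(x) length(x@reports))

#' @describeIn EcgDataset subset by report index.
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EcgDataset", function(x, i, j, ..., drop = FALSE) {
  new("EcgDataset", reports = x@reports[i],
      manifest = x@manifest[i, , drop = FALSE])
})

#' @describeIn EcgDataset integer vector of outcome labels.
#' @param object an EcgDataset.
#' @export
setMethod("labels", "EcgDataset", function(object, ...) {
  vapply(object@reports, function(r) r@label, integer(1))
})

#' Accessors for EcgReport and EcgDataset components
#'
#' @param x an \linkS4class{EcgReport}.
#' @return \code{pixels} returns the 0-255 intensity matrix, \code{reportLabel}
#'   the 0/1 outcome, \code{groundTruthMasks} the named list of logical masks,
#'   \code{manifest} the generation manifest of a dataset.
#' @export
pixels <- function(x) x@pixels

#' @rdname pixels
#' @export
reportLabel <- function(x) x@label

#' @rdname pixels
#' @export
groundTruthMasks <- function(x) x@masks

#' @rdname pixels
#' @export
manifest <- function(x) x@manifest
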