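# Dataset I/O: PNG images plus a sidecar CSV manifest.

#' Write an ECG dataset to disk
#'
#' Writes one grayscale PNG per report plus sidecar manifests
#' (\code{manifest.csv} and \code{manifest.json}) recording path, label,
#' generating parameters and per-image seed. Ground-truth masks
#' are not serialized; they live with the in-memory objects (and can always
#' be regenerated from the manifest seeds).
#'
#' @param ds an \linkS4class{EcgDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest with a \code{path} column.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds@manifest
  man$path <- file.path(dir, paste0(man$id, ".png"))
  for (i in seq_len(length(ds)))
    png::writePNG(ds@reports[[i]]@pixels / 255, man$path[i])
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read an ECG dataset from disk
#'
#' Reads \code{manifest.csv} and the PNGs it points to. Reports read back
#' carry no ground-truth masks and no waveform specs (only the manifest
#' parameters), but identical pixels and labels.
#'
#' @param dir directory written by \code{\link{writeDataset}}.
#' @param layout the \linkS4class{ReportLayout} the images were rendered
#'   with; inferred from the first image's size when NULL (panel geometry
#'   then follows the desk/default presets).
#' @return An \linkS4class{EcgDataset}.
#' @export
readDataset <- function(dir, layout = NULL) {
  manPath <- file.path(dir, "manifest.csv")
  man <- if (file.exists(manPath)) {
    utils::read.csv(manPath)
  } else if (file.exists(file.path(dir, "manifest.json"))) {
    as.data.frame(jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
  } else stop("no manifest.csv or manifest.json under ", dir)
  reports <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    px <- png::readPNG(man$path[i])
    if (length(dim(px)) == 3L) px <- px[, , 1]
    px <- round(px * 255)
    if (is.null(layout)) {
      layout <- if (ncol(px) <= 256) deskLayout() else reportLayout()
      layout@imageHeight <- nrow(px); layout@imageWidth <- ncol(px)
    }
    reports[[i]] <- new("EcgReport", pixels = px,
                        label = as.integer(man$label[i]), specs = list(),
                        layout = layout, masks = list())
  }
  new("EcgDataset", reports = reports, manifest = man)
}

#' Write a Grad-CAM overlay heatmap as PNG
#'
#' Renders the input in gray with the above-threshold saliency cells marked
#' in red.
#'
#' @param cam a \code{GradCamMap} from \code{\link{gradCam}}.
#' @param image the input image the map belongs to (matrix in [0, 1]).
#' @param path output PNG path.
#' @return invisibly, the RGB array written.
#' @export
writeCamOverlay <- function(cam, image, path) {
  g <- pmin(pmax(image, 0), 1)
  rgb <- array(rep(g, 3), c(dim(g), 3))
  ov <- cam$overlay
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[ov] <- 1; gg[ov] <- gg[ov] * 0.3; b[ov] <- b[ov] * 0.3
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(rgb)
}
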