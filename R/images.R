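# 2-D export: window (or hard-threshold) HU slices into 8-bit PNG/JPEG.

# round-half-up, elementwise (R's round() halves to even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Map an HU matrix to 8-bit display intensities
#'
#' Linear windowing: `intensity = round(255 * (HU - huMin) / (huMax -
#' huMin))`, clipped to 0..255, with half-way values rounded up. In binary
#' mode the output is 0 below `huMin` and 255 at or above it.
#'
#' @param huMatrix numeric matrix, HU (finite).
#' @param window a [WindowSpec-class].
#' @return integer matrix of intensities in 0..255.
#' @export
windowToIntensity <- function(huMatrix, window = windowSpec()) {
  stopifnot(is(window, "WindowSpec"), all(is.finite(huMatrix)))
  if (window@binary) {
    v <- ifelse(huMatrix >= window@huMin, 255L, 0L)
  } else {
    v <- .roundHalfUp(255 * (huMatrix - window@huMin) /
                        (window@huMax - window@huMin))
    v <- pmin(pmax(v, 0), 255)
  }
  matrix(as.integer(v), nrow = nrow(huMatrix))
}

#' Write an HU matrix as an 8-bit grayscale image
#'
#' Windows the matrix with [windowToIntensity()] and writes it in the
#' requested format: PNG (lossless — re-reading returns the exact 8-bit
#' matrix) or JPEG at the window's quality setting.
#'
#' @param huMatrix numeric matrix, HU.
#' @param window a [WindowSpec-class] (carries the format).
#' @param outPath output file path.
#' @return invisibly, `outPath`.
#' @export
sliceToImage <- function(huMatrix, window = windowSpec(), outPath) {
  intens <- windowToIntensity(huMatrix, window) / 255
  if (window@format == "png") {
    png::writePNG(intens, target = outPath)
  } else if (window@format == "jpeg") {
    jpeg::writeJPEG(intens, target = outPath,
                    quality = window@jpegQuality / 100)
  } else {
    stop("sliceToImage: unsupported format: ", window@format)
  }
  invisible(outPath)
}

#' Export every slice of a series as 2-D images
#'
#' Writes one image per valid slice of a sorted (and normally denoised)
#' series, filenames carrying the instance number
#' (`slice_<instance>.<ext>`). Unreadable files are reported, not fatal.
#'
#' @param seriesDir sorted series directory.
#' @param window a [WindowSpec-class].
#' @param outDir output directory (created if needed).
#' @return character vector of written files (invisibly also reports
#'   skipped inputs via the `"skipped"` attribute).
#' @export
exportSeriesImages <- function(seriesDir, window = windowSpec(), outDir) {
  if (!dir.exists(seriesDir))
    stop("exportSeriesImages: no such directory: ", seriesDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- .listStudyFiles(seriesDir)
  ext <- if (window@format == "png") "png" else "jpg"
  written <- character(); skipped <- character()
  for (f in files) {
    if (classifyFile(f)@status != "valid") {
      skipped <- c(skipped, f)
      next
    }
    s <- readSlice(f)
    inst <- if (is.na(s@instanceNumber)) match(f, files) else
      s@instanceNumber
    out <- file.path(outDir, sprintf("slice_%04d.%s", inst, ext))
    sliceToImage(huMatrix(s), window, out)
    written <- c(written, out)
  }
  structure(written, skipped = skipped)
}
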