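# Couch/noise removal: threshold for patient tissue, keep the largest
# connected component, fill its holes, zero everything outside it, and
# overwrite the DICOM file in place.

#' Threshold a Hounsfield matrix for patient tissue
#'
#' Elementwise band test: `TRUE` iff `tissueLower <= HU <= tissueUpper`.
#'
#' @param huMatrix numeric matrix in HU (finite).
#' @param spec a [ThresholdSpec-class].
#' @return logical matrix of the same dimensions.
#' @export
tissueThreshold <- function(huMatrix, spec = thresholdSpec()) {
  stopifnot(is(spec, "ThresholdSpec"), all(is.finite(huMatrix)))
  huMatrix >= spec@tissueLower & huMatrix <= spec@tissueUpper
}

# closing -> label -> largest component -> fill holes, on a 0/1 matrix
.largestComponentFilled <- function(binary, closeRadius) {
  if (closeRadius > 0) {
    kern <- EBImage::makeBrush(2L * closeRadius + 1L, shape = "disc")
    binary <- EBImage::closing(binary, kern)
  }
  lab <- EBImage::bwlabel(binary)
  nlab <- max(lab)
  if (nlab == 0L) return(binary > 0)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which.max(areas)
  EBImage::fillHull(lab == keep) > 0
}

#' Build the patient mask for one slice
#'
#' From a thresholded binary image: morphological closing (disc of radius
#' `closeRadius` pixels), connected-component labelling, retention of the
#' single largest component by pixel area, and filling of its interior
#' holes (air-filled spaces such as lungs stay inside the patient mask).
#' Structures disconnected from the patient — the scanner couch, tubing —
#' are dropped regardless of their radiodensity.
#'
#' @param binary logical matrix from [tissueThreshold()].
#' @param closeRadius closing disc radius in pixels (default 3).
#' @param path source slice path, recorded in the provenance.
#' @param spec the [ThresholdSpec-class] used, recorded in the provenance.
#' @return a [MaskImage-class]. An all-`FALSE` input yields an all-`FALSE`
#'   mask flagged `empty` in its provenance (scan padding, not an error).
#' @export
buildPatientMask <- function(binary, closeRadius = 3L, path = NA_character_,
                             spec = NULL) {
  stopifnot(is.matrix(binary), is.logical(binary))
  if (!any(binary)) {
    return(new("MaskImage", mask = binary,
               provenance = list(path = path, spec = spec, empty = TRUE)))
  }
  mask <- .largestComponentFilled(binary * 1, as.integer(closeRadius))
  new("MaskImage", mask = mask,
      provenance = list(path = path, spec = spec, empty = FALSE))
}

#' Zero stored pixels outside a mask
#'
#' Inside the mask the stored values are untouched; outside they are set to
#' stored value 0. With the usual CT intercept of -1024 HU, stored 0 reads
#' back as air — the physically sensible background.
#'
#' @param record a [CTSlice-class].
#' @param mask a [MaskImage-class] (or logical matrix) matching the slice
#'   dimensions.
#' @return integer matrix in stored units.
#' @export
applyMask <- function(record, mask) {
  stopifnot(is(record, "CTSlice"))
  m <- if (is(mask, "MaskImage")) mask@mask else mask
  if (!all(dim(m) == dim(record@pixels)))
    stop("applyMask: mask dimensions (", paste(dim(m), collapse = "x"),
         ") do not match the slice (",
         paste(dim(record@pixels), collapse = "x"), ")")
  out <- record@pixels
  out[!m] <- 0L
  out
}

#' Denoise one DICOM slice in place
#'
#' The full per-slice chain: read, convert to HU, threshold for patient
#' tissue, build the patient mask, zero everything outside it, and
#' overwrite the original file. All non-pixel metadata and the matrix size
#' are preserved exactly. Running it twice leaves the file unchanged.
#'
#' @param path path to a valid DICOM slice.
#' @param spec a [ThresholdSpec-class].
#' @param closeRadius closing disc radius in pixels.
#' @return invisibly, a list with `path`, `status` (`"denoised"` or
#'   `"skipped"`), `empty` (degenerate slice flag) and, when skipped, the
#'   [FileClassification-class].
#' @export
denoiseSlice <- function(path, spec = thresholdSpec(), closeRadius = 3L) {
  cls <- classifyFile(path)
  if (cls@status != "valid")
    return(invisible(list(path = path, status = "skipped", empty = NA,
                          classification = cls)))
  record <- readSlice(path)
  binary <- tissueThreshold(huMatrix(record), spec)
  mask <- buildPatientMask(binary, closeRadius = closeRadius, path = path,
                           spec = spec)
  overwritePixels(record, applyMask(record, mask))
  invisible(list(path = path, status = "denoised",
                 empty = mask@provenance$empty))
}

#' Denoise a sorted series directory in place
#'
#' Applies the masking chain to every valid slice of one series. In
#' `"slice"` mode each slice gets its own 2-D patient mask. In `"volume"`
#' mode the thresholded slices are stacked, the largest 6-connected 3-D
#' component is kept, and its per-slice sections (holes filled in 2-D) are
#' applied — robust where a per-slice largest component is ambiguous
#' (e.g. slices through the legs).
#'
#' @param seriesDir directory holding one sorted series.
#' @param spec a [ThresholdSpec-class].
#' @param mode `"slice"` or `"volume"`.
#' @param closeRadius closing disc radius in pixels.
#' @return data frame reporting per file: `path`, `status`, `empty`.
#' @export
denoiseSeries <- function(seriesDir, spec = thresholdSpec(),
                          mode = c("slice", "volume"), closeRadius = 3L) {
  mode <- match.arg(mode)
  if (!dir.exists(seriesDir))
    stop("denoiseSeries: no such directory: ", seriesDir)
  files <- .listStudyFiles(seriesDir)
  if (!length(files))
    return(data.frame(path = character(), status = character(),
                      empty = logical()))
  status <- vapply(files, function(f) classifyFile(f)@status, "")
  valid <- files[status == "valid"]
  slices <- lapply(valid, readSlice)
  uids <- unique(vapply(slices, function(s) s@seriesUID, ""))
  if (length(uids) > 1L)
    stop("denoiseSeries: directory mixes ", length(uids),
         " series; run sortStudy() first (no file was modified)")

  rows <- list()
  for (f in files[status != "valid"])
    rows[[f]] <- data.frame(path = f, status = "skipped", empty = NA)

  if (mode == "slice" || length(valid) < 2L) {
    for (i in seq_along(valid)) {
      r <- denoiseSlice(valid[i], spec, closeRadius)
      rows[[valid[i]]] <- data.frame(path = valid[i], status = r$status,
                                     empty = r$empty)
    }
  } else {
    d <- dim(slices[[1L]]@pixels)
    closed <- array(FALSE, c(d, length(slices)))
    kern <- EBImage::makeBrush(2L * as.integer(closeRadius) + 1L, "disc")
    for (i in seq_along(slices)) {
      b <- tissueThreshold(huMatrix(slices[[i]]), spec)
      if (!all(dim(b) == d))
        stop("denoiseSeries: inconsistent matrix sizes in series")
      closed[, , i] <- EBImage::closing(b * 1, kern) > 0
    }
    lab <- .label3dCore(as.logical(closed), dim(closed))
    nlab <- max(lab)
    if (nlab > 0L) {
      areas <- tabulate(lab[lab > 0L], nbins = nlab)
      keep3d <- array(lab == which.max(areas), dim(closed))
    } else keep3d <- array(FALSE, dim(closed))
    for (i in seq_along(slices)) {
      sec <- keep3d[, , i]
      empty <- !any(sec)
      mask <- if (empty) sec else EBImage::fillHull(sec * 1) > 0
      overwritePixels(slices[[i]], applyMask(slices[[i]], mask))
      rows[[valid[i]]] <- data.frame(path = valid[i], status = "denoised",
                                     empty = empty)
    }
  }
  out <- do.call(rbind, rows[files])
  rownames(out) <- NULL
  out
}
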