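# Series stacking, NIfTI export and output collection.

#' Stack one sorted series into a CT volume
#'
#' Reads every slice of a single-series directory, orders the slices
#' geometrically (by the projection of their positions onto the slice
#' normal — robust to reversed acquisitions; a mismatch with the
#' instance-number order is reported as a message), converts stored values
#' to HU, and builds the voxel-to-world affine in the RAS convention. DICOM
#' positions are in the patient LPS frame; the conversion negates the first
#' two world axes in the affine, never flips voxel data.
#'
#' Inter-slice spacing must be uniform to 1e-3 mm: gaps are a hard error
#' (naming the offending pair) rather than a silent resample, which would
#' corrupt downstream morphometry.
#'
#' @param seriesDir sorted single-series directory with >= 2 slices.
#' @return a [CTVolume-class].
#' @export
stackSeries <- function(seriesDir) {
  if (!dir.exists(seriesDir))
    stop("stackSeries: no such directory: ", seriesDir)
  files <- .listStudyFiles(seriesDir)
  files <- files[vapply(files, function(f)
    classifyFile(f)@status == "valid", TRUE)]
  if (length(files) < 2L)
    stop("stackSeries: need at least 2 valid slices, found ",
         length(files))
  slices <- lapply(files, readSlice)
  uids <- unique(vapply(slices, function(s) s@seriesUID, ""))
  if (length(uids) > 1L)
    stop("stackSeries: directory mixes ", length(uids), " series")
  orient <- slices[[1L]]@imageOrientation
  for (s in slices)
    if (max(abs(s@imageOrientation - orient)) > 1e-4)
      stop("stackSeries: mixed image orientations in series")
  d <- dim(slices[[1L]]@pixels)
  for (s in slices)
    if (!all(dim(s@pixels) == d))
      stop("stackSeries: inconsistent matrix sizes in series")

  rowDir <- orient[, 1L]; colDir <- orient[, 2L]
  normal <- c(rowDir[2L] * colDir[3L] - rowDir[3L] * colDir[2L],
              rowDir[3L] * colDir[1L] - rowDir[1L] * colDir[3L],
              rowDir[1L] * colDir[2L] - rowDir[2L] * colDir[1L])
  proj <- vapply(slices, function(s) sum(s@imagePosition * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]; files <- files[ord]
  inst <- vapply(slices, function(s) s@instanceNumber, 1L)
  if (!anyNA(inst) && is.unsorted(inst) && is.unsorted(rev(inst)))
    message("stackSeries: geometric order differs from instance order")

  steps <- diff(proj)
  if (any(steps <= 0))
    stop("stackSeries: duplicate slice positions in series")
  step <- steps[1L]
  bad <- which(abs(steps - step) > 1e-3)
  if (length(bad))
    stop(sprintf(
      "stackSeries: non-uniform slice spacing between %s and %s (%.4f mm vs %.4f mm)",
      basename(files[bad[1L]]), basename(files[bad[1L] + 1L]),
      steps[bad[1L]], step))

  vox <- array(0, c(d[1L], d[2L], length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- huMatrix(slices[[i]])

  sp <- slices[[1L]]@pixelSpacing
  affLPS <- cbind(c(colDir * sp[1L], 0),      # voxel row index step
                  c(rowDir * sp[2L], 0),      # voxel column index step
                  c(normal * step, 0),        # slice index step
                  c(slices[[1L]]@imagePosition, 1))
  lpsToRas <- diag(c(-1, -1, 1, 1))
  new("CTVolume", voxels = vox, affine = lpsToRas %*% affLPS,
      spacing = c(sp[1L], sp[2L], step))
}

#' Write a CT volume as a NIfTI-1 file
#'
#' Single-file NIfTI-1, HU stored as signed 16-bit with scale slope 1 and
#' intercept 0 (the voxels already are HU). The volume affine becomes both
#' the qform and sform. Re-reading returns the voxel grid elementwise and
#' the affine to within 1e-4.
#'
#' @param volume a [CTVolume-class].
#' @param outPath output path; use a `.nii.gz` suffix (or `compress =
#'   TRUE`) for compressed output.
#' @param compress write gzip-compressed NIfTI.
#' @return invisibly, the path written.
#' @export
writeVolumeNifti <- function(volume, outPath, compress = FALSE) {
  stopifnot(is(volume, "CTVolume"))
  if (compress && !grepl("\\.nii\\.gz$", outPath))
    outPath <- sub("(\\.nii)?$", ".nii.gz", outPath)
  dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(volume@voxels, datatype = "int16")
  img <- RNifti::`sform<-`(img, value = structure(volume@affine, code = 2L))
  RNifti::writeNifti(img, outPath)
  invisible(outPath)
}

#' Read a NIfTI file back as a CT volume
#'
#' Convenience inverse of [writeVolumeNifti()] (used for round-trip
#' checking and downstream meshing from saved volumes).
#'
#' @param path NIfTI file.
#' @return a [CTVolume-class].
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  aff <- if (h$sform_code > 0L)
    rbind(h$srow_x, h$srow_y, h$srow_z, c(0, 0, 0, 1))
  else {
    x <- unclass(RNifti::xform(img))
    attributes(x) <- list(dim = dim(x))
    x
  }
  dimnames(aff) <- NULL
  new("CTVolume", voxels = array(as.numeric(img), dim(img)), affine = aff,
      spacing = sqrt(colSums(aff[1:3, 1:3]^2)))
}

#' Collect NIfTI outputs into one directory
#'
#' Moves every `.nii`/`.nii.gz` file found under `searchRoot` into `dest`,
#' suffixing names on collision (`name-2.nii`, ...).
#'
#' @param searchRoot directory to search recursively.
#' @param dest destination directory (created if needed).
#' @return character vector of the new paths (empty when nothing found).
#' @export
collectOutputs <- function(searchRoot, dest) {
  if (!dir.exists(searchRoot))
    stop("collectOutputs: no such directory: ", searchRoot)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  found <- list.files(searchRoot, pattern = "\\.nii(\\.gz)?$",
                      recursive = TRUE, full.names = TRUE)
  found <- found[normalizePath(dirname(found)) != normalizePath(dest)]
  moved <- character()
  for (f in found) {
    base <- basename(f)
    ext <- if (grepl("\\.nii\\.gz$", base)) ".nii.gz" else ".nii"
    stem <- sub("\\.nii(\\.gz)?$", "", base)
    target <- file.path(dest, base); k <- 1L
    while (file.exists(target)) {
      k <- k + 1L
      target <- file.path(dest, paste0(stem, "-", k, ext))
    }
    if (!file.rename(f, target)) {
      file.copy(f, target)
      unlink(f)
    }
    moved <- c(moved, target)
  }
  moved
}
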