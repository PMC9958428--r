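# Synthetic CT phantom studies with analytic ground truth.
#
# The phantom emulates a clinical CT acquisition: 12-bit unsigned stored
# pixels with linear rescale (slope 1, intercept -1024), per-slice geometry
# tags, several interleaved series per study directory, an elliptical
# soft-tissue body with bone-density inserts, and a couch/table arc outside
# the body. Material boundaries are rendered with a linear partial-volume
# edge ramp of fixed physical width (finite scanner PSF): CT edges are never
# step functions, and a one-voxel ramp at the default 0.5 mm grid is the
# partial-volume minimum.

.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Describe a synthetic CT phantom study
#'
#' Defaults mirror a typical clinical acquisition regime: 512 x 512 matrix,
#' 0.5 mm pixel spacing and slice thickness, soft tissue at 40 HU, bone
#' inserts at 700 HU, and a couch arc at 150 HU — deliberately inside the
#' tissue-detection band, so removing it genuinely exercises the
#' connected-component logic rather than thresholding alone.
#'
#' @param matrixSize,nSlices,nSeries study dimensions.
#' @param pixelSpacing,sliceThickness mm.
#' @param bodySemiAxes ellipse semi-axes (x, y) in mm.
#' @param bodyHU,boneHU,tableHU,airHU material radiodensities, HU.
#' @param boneInserts list of inserts (see [PhantomSpec-class]); the default
#'   places one sphere and one cylinder inside the body.
#' @param tableRadius,tableWidth,tableHalfAngle couch arc geometry: mid
#'   radius and radial width in mm, half angular span in degrees about the
#'   posterior direction. Must clear the body.
#' @param edgeWidth partial-volume edge ramp width, mm.
#' @param noiseSD additive Gaussian noise in HU (before quantisation).
#' @param seed integer; fully determines the emitted bytes.
#' @param decoyNonDicom,decoyCorrupted number of decoy files to emit.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(matrixSize = 512L, nSlices = 16L, nSeries = 1L,
                        pixelSpacing = 0.5, sliceThickness = 0.5,
                        bodySemiAxes = c(80, 60),
                        bodyHU = 40, boneHU = 700, tableHU = 150,
                        airHU = -1000,
                        boneInserts = NULL,
                        tableRadius = 95, tableWidth = 6,
                        tableHalfAngle = 50,
                        edgeWidth = 0.5, noiseSD = 0, seed = 1L,
                        decoyNonDicom = 0L, decoyCorrupted = 0L) {
  zMid <- nSlices * sliceThickness / 2
  if (is.null(boneInserts)) {
    rBone <- min(bodySemiAxes) * 0.2
    boneInserts <- list(
      list(type = "sphere", center = c(bodySemiAxes[1] * 0.45, 0, zMid),
           radius = rBone),
      list(type = "cylinder", center = c(-bodySemiAxes[1] * 0.45, 0, zMid),
           radius = rBone * 0.7, halfLength = zMid))
  }
  new("PhantomSpec",
      matrixSize = as.integer(matrixSize), nSlices = as.integer(nSlices),
      nSeries = as.integer(nSeries),
      pixelSpacing = pixelSpacing, sliceThickness = sliceThickness,
      bodySemiAxes = bodySemiAxes,
      bodyHU = bodyHU, boneHU = boneHU, tableHU = tableHU, airHU = airHU,
      boneInserts = boneInserts,
      tableRadius = tableRadius, tableWidth = tableWidth,
      tableHalfAngle = tableHalfAngle,
      edgeWidth = edgeWidth, noiseSD = noiseSD, seed = as.integer(seed),
      decoyNonDicom = as.integer(decoyNonDicom),
      decoyCorrupted = as.integer(decoyCorrupted))
}

# In-plane coordinate grids (mm) for pixel centres; row index -> y, column
# index -> x, matching the DICOM orientation written by the generator.
.phantomGrid <- function(spec) {
  n <- spec@matrixSize
  coords <- ((seq_len(n) - 1) - (n - 1) / 2) * spec@pixelSpacing
  list(x = matrix(coords, n, n, byrow = TRUE),
       y = matrix(coords, n, n, byrow = FALSE),
       origin = coords[1])
}

# Approximate signed distance (mm) to the body ellipse boundary; negative
# inside. Gradient-normalised implicit function, exact on the axes.
.bodyDistance <- function(x, y, ab) {
  a <- ab[1]; b <- ab[2]
  rho <- sqrt((x / a)^2 + (y / b)^2)
  g <- sqrt((x / a^2)^2 + (y / b^2)^2)
  (rho - 1) * pmax(rho, 1e-9) / pmax(g, 1e-12)
}

.tableDistance <- function(x, y, spec) {
  rr <- sqrt(x^2 + y^2)
  dRad <- abs(rr - spec@tableRadius) - spec@tableWidth / 2
  ang <- abs(atan2(x, y))                       # 0 along +y (posterior)
  dAng <- (ang - spec@tableHalfAngle * pi / 180) * pmax(rr, 1e-9)
  pmax(dRad, dAng)
}

.insertDistance <- function(ins, x, y, z) {
  cx <- ins$center[1]; cy <- ins$center[2]; cz <- ins$center[3]
  if (identical(ins$type, "cylinder")) {
    dr <- sqrt((x - cx)^2 + (y - cy)^2) - ins$radius
    dz <- abs(z - cz) - ins$halfLength
    pmax(dr, dz)
  } else {
    sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2) - ins$radius
  }
}

.rampFraction <- function(d, w) pmin(pmax(0.5 - d / w, 0), 1)

# Noise-free HU image of slice k (1-based), partial-volume edges included.
.phantomSliceHU <- function(spec, k, grid = .phantomGrid(spec)) {
  z <- (k - 1) * spec@sliceThickness
  w <- spec@edgeWidth
  fBody <- .rampFraction(.bodyDistance(grid$x, grid$y, spec@bodySemiAxes), w)
  fTable <- .rampFraction(.tableDistance(grid$x, grid$y, spec), w)
  hu <- spec@airHU + (spec@bodyHU - spec@airHU) * fBody +
    (spec@tableHU - spec@airHU) * fTable
  for (ins in spec@boneInserts) {
    fIns <- .rampFraction(.insertDistance(ins, grid$x, grid$y, z), w)
    huIns <- if (is.null(ins$hu)) spec@boneHU else ins$hu
    hu <- hu + (huIns - spec@bodyHU) * fIns * fBody
  }
  hu
}

#' Analytic ground-truth masks for a phantom
#'
#' Per-slice boolean masks of the body, table and bone-insert regions,
#' computed directly from the phantom geometry (pixel centres inside each
#' structure) — independent of the pipeline's own masking code.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with 3-D logical arrays `body`, `table`, `bone`
#'   (rows x cols x slices).
#' @export
groundTruthMasks <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  grid <- .phantomGrid(spec)
  n <- spec@matrixSize
  dims <- c(n, n, spec@nSlices)
  body <- array(FALSE, dims); tab <- array(FALSE, dims)
  bone <- array(FALSE, dims)
  bodySlice <- .bodyDistance(grid$x, grid$y, spec@bodySemiAxes) < 0
  tabSlice <- .tableDistance(grid$x, grid$y, spec) < 0
  for (k in seq_len(spec@nSlices)) {
    z <- (k - 1) * spec@sliceThickness
    body[, , k] <- bodySlice
    tab[, , k] <- tabSlice
    bk <- matrix(FALSE, n, n)
    for (ins in spec@boneInserts)
      bk <- bk | (.insertDistance(ins, grid$x, grid$y, z) < 0)
    bone[, , k] <- bk & bodySlice
  }
  list(body = body, table = tab, bone = bone)
}

.phantomUID <- function(seed, kind, n)
  paste0("2.25.9", seed, "0", kind, sprintf("%06d", n))

.phantomSliceObject <- function(spec, seriesIdx, seriesUID, studyUID, k,
                                stored, counter, path) {
  n <- spec@matrixSize
  origin <- .phantomGrid(spec)$origin
  z <- (k - 1) * spec@sliceThickness
  sopUID <- .phantomUID(spec@seed, 3L, counter)
  els <- list(
    .element(0x0008, 0x0016, "UI", .encString(.SOP_CT, ui = TRUE)),
    .element(0x0008, 0x0018, "UI", .encString(sopUID, ui = TRUE)),
    .element(0x0008, 0x0020, "DA", .encString("20230101")),
    .element(0x0008, 0x0021, "DA", .encString("20230101")),
    .element(0x0008, 0x0060, "CS", .encString("CT")),
    .element(0x0010, 0x0010, "PN", .encString("PHANTOM^SYNTHETIC")),
    .element(0x0010, 0x0020, "LO", .encString("PHANTOM")),
    .element(0x0010, 0x0040, "CS", .encString("O")),
    .element(0x0010, 0x1010, "AS", .encString("040Y")),
    .element(0x0018, 0x0050, "DS", .encDS(spec@sliceThickness)),
    .element(0x0018, 0x0060, "DS", .encDS(120)),
    .element(0x0020, 0x000D, "UI", .encString(studyUID, ui = TRUE)),
    .element(0x0020, 0x000E, "UI", .encString(seriesUID, ui = TRUE)),
    .element(0x0020, 0x0011, "IS", .encIS(seriesIdx)),
    .element(0x0020, 0x0013, "IS", .encIS(k)),
    .element(0x0020, 0x0032, "DS", .encDS(c(origin, origin, z))),
    .element(0x0020, 0x0037, "DS", .encDS(c(1, 0, 0, 0, 1, 0))),
    .element(0x0028, 0x0002, "US", .encUSval(1L)),
    .element(0x0028, 0x0004, "CS", .encString("MONOCHROME2")),
    .element(0x0028, 0x0010, "US", .encUSval(n)),
    .element(0x0028, 0x0011, "US", .encUSval(n)),
    .element(0x0028, 0x0030, "DS", .encDS(rep(spec@pixelSpacing, 2L))),
    .element(0x0028, 0x0100, "US", .encUSval(16L)),
    .element(0x0028, 0x0101, "US", .encUSval(12L)),
    .element(0x0028, 0x0102, "US", .encUSval(11L)),
    .element(0x0028, 0x0103, "US", .encUSval(0L)),
    .element(0x0028, 0x1052, "DS", .encDS(-1024)),
    .element(0x0028, 0x1053, "DS", .encDS(1)))
  new("CTSlice",
      pixels = stored,
      rescaleSlope = 1, rescaleIntercept = -1024,
      pixelSpacing = rep(spec@pixelSpacing, 2L),
      sliceThickness = spec@sliceThickness,
      imagePosition = c(origin, origin, z),
      imageOrientation = matrix(c(1, 0, 0, 0, 1, 0), 3L, 2L),
      seriesNumber = as.integer(seriesIdx), seriesUID = seriesUID,
      instanceNumber = as.integer(k),
      bitsAllocated = 16L, bitsStored = 12L, pixelRepresentation = 0L,
      transferSyntax = .TS_EXPLICIT_LE, sourcePath = path,
      metaElements = .buildMetaElements(sopUID, .TS_EXPLICIT_LE),
      elements = els)
}

#' Generate a synthetic CT study on disk
#'
#' Writes `nSeries * nSlices` conformant DICOM files into `outDir` with the
#' series interleaved (emulating an uncollated clinical dump), plus any
#' requested decoy files: plain-text non-DICOM decoys and truncated
#' (corrupted) DICOM decoys. The same seed always reproduces the study
#' byte-for-byte.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir directory to create/populate.
#' @param truthDir optional directory; when given, ground-truth masks are
#'   written there as NIfTI files plus a JSON manifest. Kept outside
#'   `outDir` so study-directory operations never see them.
#' @return invisibly, a data frame describing every emitted file: `path`,
#'   `kind` (`slice`, `decoy_non_dicom`, `decoy_corrupted`), `series`,
#'   `instance`.
#' @export
makePhantomStudy <- function(spec, outDir, truthDir = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- .phantomGrid(spec)
  sliceHU <- lapply(seq_len(spec@nSlices), .phantomSliceHU, spec = spec,
                    grid = grid)
  studyUID <- .phantomUID(spec@seed, 1L, 1L)
  seriesUIDs <- vapply(seq_len(spec@nSeries),
                       function(s) .phantomUID(spec@seed, 2L, s), "")
  records <- list()
  .withSeed(spec@seed, {
    counter <- 0L
    # interleave: instance-major so consecutive files alternate series
    for (k in seq_len(spec@nSlices)) {
      for (s in seq_len(spec@nSeries)) {
        counter <- counter + 1L
        hu <- sliceHU[[k]]
        if (spec@noiseSD > 0)
          hu <- hu + matrix(rnorm(length(hu), sd = spec@noiseSD),
                            nrow = nrow(hu))
        stored <- huToStored(hu, 1, -1024, bitsStored = 12L,
                             pixelRepresentation = 0L)
        path <- file.path(outDir, sprintf("IM%06d.dcm", counter))
        slice <- .phantomSliceObject(spec, s, seriesUIDs[s], studyUID, k,
                                     stored, counter, path)
        .writeSliceFile(slice, path)
        records[[length(records) + 1L]] <-
          data.frame(path = path, kind = "slice", series = s, instance = k)
      }
    }
    for (i in seq_len(spec@decoyNonDicom)) {
      path <- file.path(outDir, sprintf("decoy%03d.txt", i))
      writeLines(c("not a DICOM file", paste("decoy", i)), path)
      records[[length(records) + 1L]] <-
        data.frame(path = path, kind = "decoy_non_dicom", series = NA,
                   instance = NA)
    }
    for (i in seq_len(spec@decoyCorrupted)) {
      counter <- counter + 1L
      hu <- sliceHU[[1L]]
      stored <- huToStored(hu, 1, -1024, 12L, 0L)
      path <- file.path(outDir, sprintf("trunc%03d.dcm", i))
      slice <- .phantomSliceObject(spec, 1L, seriesUIDs[1L], studyUID, 1L,
                                   stored, counter, path)
      .writeSliceFile(slice, path)
      bytes <- readBin(path, "raw", n = file.size(path))
      con <- file(path, "wb")
      writeBin(bytes[seq_len(length(bytes) %/% 2L)], con)
      close(con)
      records[[length(records) + 1L]] <-
        data.frame(path = path, kind = "decoy_corrupted", series = NA,
                   instance = NA)
    }
  })
  manifest <- do.call(rbind, records)
  if (!is.null(truthDir)) {
    dir.create(truthDir, recursive = TRUE, showWarnings = FALSE)
    truth <- groundTruthMasks(spec)
    for (nm in names(truth))
      RNifti::writeNifti(RNifti::asNifti(truth[[nm]] * 1L),
                         file.path(truthDir, paste0("truth_", nm, ".nii")))
    jsonlite::write_json(
      list(seed = spec@seed, nSeries = spec@nSeries, nSlices = spec@nSlices,
           matrixSize = spec@matrixSize, pixelSpacing = spec@pixelSpacing,
           sliceThickness = spec@sliceThickness, noiseSD = spec@noiseSD,
           seriesUIDs = seriesUIDs, files = manifest),
      file.path(truthDir, "truth_manifest.json"), auto_unbox = TRUE)
  }
  invisible(manifest)
}

#' Calibrated sphere volume for surface-accuracy checks
#'
#' Builds a [CTVolume-class] sampling a clamped linear radial ramp between
#' an outside and an inside radiodensity, calibrated so the `iso` level set
#' of the continuous field lies exactly on the stated sphere. This is the
#' standard fixture for checking isosurface area/volume against the analytic
#' sphere: a hard binary sphere would measure the staircase bias of binary
#' fields rather than the extraction error.
#'
#' @param radius sphere radius, mm.
#' @param spacing isotropic voxel spacing, mm.
#' @param insideHU,outsideHU plateau radiodensities, HU.
#' @param iso the HU level whose surface is placed at `radius`.
#' @param edgeWidth ramp width, mm.
#' @param margin grid padding beyond the sphere, mm.
#' @return a [CTVolume-class] with an axis-aligned RAS affine centred on the
#'   sphere.
#' @export
sphereVolume <- function(radius = 10, spacing = 0.5, insideHU = 700,
                         outsideHU = -1000, iso = 200, edgeWidth = 1,
                         margin = 3) {
  n <- as.integer(ceiling(2 * (radius + margin) / spacing)) + 1L
  coords <- ((seq_len(n) - 1) - (n - 1) / 2) * spacing
  d <- sqrt(outer(outer(coords^2, coords^2, "+"), coords^2, "+")) - radius
  k <- (insideHU - outsideHU) / edgeWidth
  vox <- pmin(pmax(iso - k * d, outsideHU), insideHU)
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- coords[1]
  new("CTVolume", voxels = vox, affine = aff, spacing = rep(spacing, 3))
}
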