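# S4 classes for the CT pre-processing pipeline.

#' Classification of a candidate input file
#'
#' Result of [classifyFile()]: one of `"valid"`, `"non_dicom"` or
#' `"corrupted"`, with a human-readable reason for the non-valid statuses.
#'
#' @slot status character, one of `"valid"`, `"non_dicom"`, `"corrupted"`.
#' @slot detail character, non-empty reason when status is not `"valid"`.
#' @exportClass FileClassification
setClass("FileClassification",
  representation(status = "character", detail = "character"),
  validity = function(object) {
    if (length(object@status) != 1L ||
        !object@status %in% c("valid", "non_dicom", "corrupted"))
      return("status must be one of 'valid', 'non_dicom', 'corrupted'")
    if (object@status != "valid" && !nzchar(object@detail))
      return("detail must be non-empty for non-valid classifications")
    TRUE
  })

#' One decoded CT slice
#'
#' A single DICOM image slice: the stored pixel matrix plus the geometry,
#' rescale and series metadata the pipeline consumes. All remaining metadata
#' elements are preserved verbatim (raw bytes, original order) in
#' `@elements`, so a slice can be re-written without touching attributes the
#' pipeline does not interpret.
#'
#' Stored pixel values map to Hounsfield units through the linear rescale
#' `HU = stored * slope + intercept` (see [storedToHU()]).
#'
#' @slot pixels integer matrix (rows x cols) in scanner stored units.
#' @slot rescaleSlope,rescaleIntercept numeric, the linear HU rescale.
#' @slot pixelSpacing numeric length 2, mm between rows and between columns.
#' @slot sliceThickness numeric, mm (`NA` when the file does not carry it).
#' @slot imagePosition numeric length 3, mm, patient (LPS) frame.
#' @slot imageOrientation 3 x 2 matrix; columns are the row-direction and
#'   column-direction unit vectors in the patient frame.
#' @slot seriesNumber,instanceNumber integer (`NA` allowed for either).
#' @slot seriesUID character, Series Instance UID.
#' @slot bitsAllocated,bitsStored,pixelRepresentation integer; stored-value
#'   encoding (16/12/unsigned for typical CT).
#' @slot transferSyntax character, UID of the encoding the file used.
#' @slot sourcePath character, where the slice was read from.
#' @slot metaElements,elements lists of raw DICOM elements (file meta group
#'   and main data set, pixel data excluded) for lossless re-writing.
#' @exportClass CTSlice
setClass("CTSlice",
  representation(
    pixels = "matrix",
    rescaleSlope = "numeric", rescaleIntercept = "numeric",
    pixelSpacing = "numeric", sliceThickness = "numeric",
    imagePosition = "numeric", imageOrientation = "matrix",
    seriesNumber = "integer", seriesUID = "character",
    instanceNumber = "integer",
    bitsAllocated = "integer", bitsStored = "integer",
    pixelRepresentation = "integer",
    transferSyntax = "character", sourcePath = "character",
    metaElements = "list", elements = "list"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (d[1] <= 0L || d[2] <= 0L) return("pixel matrix must be non-empty")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
      return("pixel spacings must be positive")
    if (!is.na(object@sliceThickness) && object@sliceThickness <= 0)
      return("slice thickness must be positive when present")
    if (length(object@imagePosition) != 3L)
      return("image position must be a 3-vector")
    o <- object@imageOrientation
    if (!all(dim(o) == c(3L, 2L))) return("orientation must be 3 x 2")
    n1 <- sqrt(sum(o[, 1]^2)); n2 <- sqrt(sum(o[, 2]^2))
    if (abs(n1 - 1) > 1e-4 || abs(n2 - 1) > 1e-4)
      return("orientation vectors must have unit norm (tol 1e-4)")
    if (abs(sum(o[, 1] * o[, 2])) > 1e-4)
      return("orientation vectors must be orthogonal (tol 1e-4)")
    if (object@rescaleSlope == 0) return("rescale slope must be non-zero")
    if (is.na(object@seriesNumber) && !nzchar(object@seriesUID))
      return("slice needs a series number or a series UID")
    TRUE
  })

#' Patient mask for one slice
#'
#' Boolean matrix marking patient tissue, produced by [buildPatientMask()].
#' `provenance` records the source slice path, the [ThresholdSpec] used and
#' whether the slice was degenerate (no tissue found).
#'
#' @slot mask logical matrix, same dimensions as the slice pixel matrix.
#' @slot provenance list with elements `path`, `spec`, `empty`.
#' @exportClass MaskImage
setClass("MaskImage",
  representation(mask = "matrix", provenance = "list"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask entries must be boolean")
    if (anyNA(object@mask)) return("mask entries must not be NA")
    TRUE
  })

#' Hounsfield thresholding bands
#'
#' The two HU bands the pipeline uses: `tissueLower..tissueUpper` detects the
#' patient for masking (wide: soft tissue through cortical bone), and
#' `boneLower..boneUpper` selects bone for 2-D thresholded export and as the
#' default isosurface level. Always expressed in HU, never stored units.
#'
#' @slot tissueLower,tissueUpper,boneLower,boneUpper numeric, HU.
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(tissueLower = "numeric", tissueUpper = "numeric",
                 boneLower = "numeric", boneUpper = "numeric"),
  validity = function(object) {
    if (object@tissueLower >= object@tissueUpper)
      return("tissueLower must be < tissueUpper")
    if (object@boneLower >= object@boneUpper)
      return("boneLower must be < boneUpper")
    TRUE
  })

#' HU-to-intensity window for 2-D export
#'
#' Linear map of `[huMin, huMax]` onto display intensities 0..255 with
#' clipping; `binary = TRUE` switches to hard thresholding (0/255 at
#' `huMin`).
#'
#' @slot huMin,huMax numeric, HU mapped to 0 and 255.
#' @slot format character, `"png"` or `"jpeg"`.
#' @slot jpegQuality integer 1..100.
#' @slot binary logical, hard-threshold mode.
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(huMin = "numeric", huMax = "numeric", format = "character",
                 jpegQuality = "integer", binary = "logical"),
  validity = function(object) {
    if (object@huMin >= object@huMax) return("huMin must be < huMax")
    if (!object@format %in% c("png", "jpeg"))
      return("format must be 'png' or 'jpeg'")
    if (object@jpegQuality < 1L || object@jpegQuality > 100L)
      return("jpegQuality must be in 1..100")
    TRUE
  })

#' A reconstructed CT volume
#'
#' One series stacked into a 3-D Hounsfield grid with a voxel-index-to-world
#' affine in the RAS convention (x right, y anterior, z superior), as used by
#' NIfTI. Voxel index order is (row, column, slice), zero-based in the
#' affine.
#'
#' @slot voxels 3-D numeric array (rows x cols x slices), HU.
#' @slot affine 4 x 4 matrix, zero-based voxel index to world mm (RAS).
#' @slot spacing numeric length 3, mm per axis (row, col, slice).
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", affine = "matrix", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be 3-D")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4 x 4")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    norms <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(abs(norms - object@spacing) > 1e-4))
      return("affine column norms must equal spacing (tol 1e-4)")
    TRUE
  })

#' Triangle surface mesh
#'
#' The STL payload: vertices in world mm, triangle index triples with
#' consistent outward winding, and per-triangle unit normals.
#'
#' @slot vertices n x 3 numeric matrix, mm, world frame.
#' @slot triangles m x 3 integer matrix, 1-based vertex indices.
#' @slot normals m x 3 numeric matrix, unit outward normals.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 normals = "matrix"),
  validity = function(object) {
    nt <- nrow(object@triangles)
    if (ncol(object@vertices) != 3L && nrow(object@vertices) > 0L)
      return("vertices must be n x 3")
    if (nt > 0L) {
      if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
      idx <- range(object@triangles)
      if (idx[1] < 1L || idx[2] > nrow(object@vertices))
        return("triangle indices out of range")
      if (nrow(object@normals) != nt) return("one normal per triangle")
      nn <- sqrt(rowSums(object@normals^2))
      if (any(abs(nn - 1) > 1e-5))
        return("normals must be unit length (tol 1e-5)")
    }
    TRUE
  })

#' Synthetic CT phantom description
#'
#' Parameters of a generated CT study: an elliptical soft-tissue body
#' cross-section with bone-density inserts, and a couch/table arc outside the
#' body, rendered into conformant DICOM slices with a linear partial-volume
#' edge ramp (finite scanner PSF) and optional additive Gaussian HU noise.
#' The table region is guaranteed disjoint from the body.
#'
#' @slot matrixSize integer, pixels per in-plane dimension.
#' @slot nSlices,nSeries integer.
#' @slot pixelSpacing,sliceThickness numeric, mm.
#' @slot bodySemiAxes numeric length 2, ellipse semi-axes (x, y) mm.
#' @slot bodyHU,boneHU,tableHU,airHU numeric, HU of each material.
#' @slot boneInserts list of inserts, each a list with `type` ("sphere" or
#'   "cylinder"), `center` (mm, 3), `radius` (mm), optional `halfLength`
#'   (mm, cylinders), optional `hu`.
#' @slot tableRadius,tableWidth,tableHalfAngle numeric; the table is an
#'   annulus sector of mid radius `tableRadius`, radial width `tableWidth`,
#'   spanning `±tableHalfAngle` degrees about the posterior (+y) direction.
#' @slot edgeWidth numeric, mm, width of the partial-volume edge ramp.
#' @slot noiseSD numeric, HU, additive Gaussian noise before quantisation.
#' @slot seed integer; fully determines the emitted bytes.
#' @slot decoyNonDicom,decoyCorrupted integer, counts of decoy files.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    matrixSize = "integer", nSlices = "integer", nSeries = "integer",
    pixelSpacing = "numeric", sliceThickness = "numeric",
    bodySemiAxes = "numeric",
    bodyHU = "numeric", boneHU = "numeric", tableHU = "numeric",
    airHU = "numeric",
    boneInserts = "list",
    tableRadius = "numeric", tableWidth = "numeric",
    tableHalfAngle = "numeric",
    edgeWidth = "numeric", noiseSD = "numeric", seed = "integer",
    decoyNonDicom = "integer", decoyCorrupted = "integer"),
  validity = function(object) {
    if (object@matrixSize < 8L) return("matrixSize must be >= 8")
    if (object@nSlices < 1L || object@nSeries < 1L)
      return("need at least one slice and one series")
    if (object@pixelSpacing <= 0 || object@sliceThickness <= 0)
      return("spacings must be positive")
    hu <- c(object@bodyHU, object@boneHU, object@tableHU, object@airHU)
    if (any(hu < -1024) || any(hu > 3071))
      return("phantom HU values must lie in [-1024, 3071]")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    # table annulus must clear the body ellipse (edge ramps included)
    inner <- object@tableRadius - object@tableWidth / 2
    if (inner <= max(object@bodySemiAxes) + object@edgeWidth)
      return("table overlaps the body: increase tableRadius")
    TRUE
  })

#' Index of a sorted study
#'
#' Result of [sortStudy()]: the final per-series layout. `index` maps each
#' series key (subfolder name) to its file paths ordered by instance number;
#' `uids` gives the Series Instance UID behind each key; `collisions` lists
#' keys that needed a numeric suffix because two UIDs shared a series number.
#'
#' @slot index named list of character vectors (file paths).
#' @slot uids named character vector, series UID per key.
#' @slot collisions character vector of suffixed keys.
#' @exportClass SeriesIndex
setClass("SeriesIndex",
  representation(index = "list", uids = "character",
                 collisions = "character"),
  validity = function(object) {
    if (length(object@index) != length(object@uids))
      return("one UID per series key")
    paths <- unlist(object@index, use.names = FALSE)
    if (anyDuplicated(paths)) return("a file may appear under only one key")
    TRUE
  })
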