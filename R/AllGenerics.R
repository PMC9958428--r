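# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for pipeline objects
#' @description Slot accessors for [CTSlice-class], [CTVolume-class],
#'   [MaskImage-class] and [TriangleMesh-class] objects. Prefer these over
#'   direct slot access.
#' @param object a pipeline object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setMethod("pixelData", "CTSlice", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("huMatrix", function(object) standardGeneric("huMatrix"))
#' @rdname accessors
#' @export
setMethod("huMatrix", "CTSlice", function(object)
  storedToHU(object@pixels, object@rescaleSlope, object@rescaleIntercept))

#' @rdname accessors
#' @export
setGeneric("rescaleSlope", function(object) standardGeneric("rescaleSlope"))
#' @rdname accessors
#' @export
setMethod("rescaleSlope", "CTSlice", function(object) object@rescaleSlope)

#' @rdname accessors
#' @export
setGeneric("rescaleIntercept",
           function(object) standardGeneric("rescaleIntercept"))
#' @rdname accessors
#' @export
setMethod("rescaleIntercept", "CTSlice",
          function(object) object@rescaleIntercept)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "CTSlice", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("sliceThickness",
           function(object) standardGeneric("sliceThickness"))
#' @rdname accessors
#' @export
setMethod("sliceThickness", "CTSlice", function(object) object@sliceThickness)

#' @rdname accessors
#' @export
setGeneric("imagePosition", function(object) standardGeneric("imagePosition"))
#' @rdname accessors
#' @export
setMethod("imagePosition", "CTSlice", function(object) object@imagePosition)

#' @rdname accessors
#' @export
setGeneric("imageOrientation",
           function(object) standardGeneric("imageOrientation"))
#' @rdname accessors
#' @export
setMethod("imageOrientation", "CTSlice",
          function(object) object@imageOrientation)

#' @rdname accessors
#' @export
setGeneric("seriesNumber", function(object) standardGeneric("seriesNumber"))
#' @rdname accessors
#' @export
setMethod("seriesNumber", "CTSlice", function(object) object@seriesNumber)

#' @rdname accessors
#' @export
setGeneric("seriesUID", function(object) standardGeneric("seriesUID"))
#' @rdname accessors
#' @export
setMethod("seriesUID", "CTSlice", function(object) object@seriesUID)

#' @rdname accessors
#' @export
setGeneric("instanceNumber",
           function(object) standardGeneric("instanceNumber"))
#' @rdname accessors
#' @export
setMethod("instanceNumber", "CTSlice", function(object) object@instanceNumber)

#' @rdname accessors
#' @export
setGeneric("sourcePath", function(object) standardGeneric("sourcePath"))
#' @rdname accessors
#' @export
setMethod("sourcePath", "CTSlice", function(object) object@sourcePath)

#' Decoded non-pixel metadata of a slice
#'
#' Returns every data-set element (pixel data excluded) as a named list of
#' decoded values where the VR is a simple string or number type, and raw
#' byte vectors otherwise. Names are `GGGGEEEE` hexadecimal tag keys.
#'
#' @param object a [CTSlice-class].
#' @return named list.
#' @export
setGeneric("extraTags", function(object) standardGeneric("extraTags"))
#' @rdname extraTags
#' @export
setMethod("extraTags", "CTSlice", function(object) {
  out <- lapply(object@elements, function(el) .decodeElementValue(el))
  names(out) <- vapply(object@elements,
                       function(el) .tagKey(el$group, el$element), "")
  out
})

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "MaskImage", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "MaskImage", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("affine", function(object) standardGeneric("affine"))
#' @rdname accessors
#' @export
setMethod("affine", "CTVolume", function(object) object@affine)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "TriangleMesh", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("triangles", function(object) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setMethod("triangles", "TriangleMesh", function(object) object@triangles)

#' @rdname accessors
#' @export
setGeneric("facetNormals", function(object) standardGeneric("facetNormals"))
#' @rdname accessors
#' @export
setMethod("facetNormals", "TriangleMesh", function(object) object@normals)

#' @describeIn accessors dimensions of the stored pixel matrix.
#' @export
setMethod("dim", "CTSlice", function(x) dim(x@pixels))

#' @describeIn accessors dimensions of the voxel grid.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "FileClassification", function(object) {
  cat("FileClassification:", object@status,
      if (nzchar(object@detail)) paste0("(", object@detail, ")"), "\n")
})

setMethod("show", "CTSlice", function(object) {
  d <- dim(object@pixels)
  cat("CTSlice", paste0(d[1], "x", d[2]),
      sprintf("| series %s (#%s) instance %s\n",
              object@seriesUID, object@seriesNumber, object@instanceNumber))
  cat(sprintf("  spacing %.4g x %.4g mm, thickness %s mm\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              format(object@sliceThickness)))
  cat(sprintf("  position (%.4g, %.4g, %.4g) mm [LPS], rescale %g x + %g\n",
              object@imagePosition[1], object@imagePosition[2],
              object@imagePosition[3], object@rescaleSlope,
              object@rescaleIntercept))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat("CTVolume", paste(d, collapse = " x "),
      sprintf("voxels | spacing %s mm | HU range [%g, %g]\n",
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
})

setMethod("show", "MaskImage", function(object) {
  d <- dim(object@mask)
  cat("MaskImage", paste0(d[1], "x", d[2]), "|",
      sum(object@mask), "foreground pixels",
      if (isTRUE(object@provenance$empty)) "(degenerate: no tissue found)",
      "\n")
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: tissue [%g, %g] HU, bone [%g, %g] HU\n",
              object@tissueLower, object@tissueUpper,
              object@boneLower, object@boneUpper))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: [%g, %g] HU -> 0..255, %s%s\n",
              object@huMin, object@huMax, object@format,
              if (object@binary) " (binary threshold)" else ""))
})

setMethod("show", "SeriesIndex", function(object) {
  cat("SeriesIndex:", length(object@index), "series\n")
  for (k in names(object@index))
    cat(sprintf("  %s: %d files (UID %s)\n", k, length(object@index[[k]]),
                object@uids[[k]]))
  if (length(object@collisions))
    cat("  collisions:", paste(object@collisions, collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d series x %d slices, %dx%d px @ %g mm, noise %g HU, seed %d\n",
    object@nSeries, object@nSlices, object@matrixSize, object@matrixSize,
    object@pixelSpacing, object@noiseSD, object@seed))
})
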