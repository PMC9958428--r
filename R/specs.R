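# User-facing constructors for parameter objects.

#' Create a Hounsfield thresholding specification
#'
#' The tissue band (default -300..3000 HU, soft tissue through cortical
#' bone) drives patient detection for masking; the bone band (default
#' 200..3000 HU) drives bone-only 2-D thresholding and is the default
#' isosurface level for mesh export. Both bands are fully configurable —
#' lowering the bands highlights other tissues of interest.
#'
#' @param tissueLower,tissueUpper HU band used to detect the patient.
#' @param boneLower,boneUpper HU band for bone thresholding.
#' @return a [ThresholdSpec-class].
#' @examples
#' thresholdSpec()
#' thresholdSpec(boneLower = 300)
#' @export
thresholdSpec <- function(tissueLower = -300, tissueUpper = 3000,
                          boneLower = 200, boneUpper = 3000) {
  new("ThresholdSpec", tissueLower = tissueLower, tissueUpper = tissueUpper,
      boneLower = boneLower, boneUpper = boneUpper)
}

#' Create a display window for 2-D export
#'
#' @param huMin,huMax HU mapped to intensities 0 and 255 (default: the bone
#'   band of [thresholdSpec()]).
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @param jpegQuality integer 1..100, used for JPEG only.
#' @param binary if `TRUE`, hard-threshold at `huMin`: intensities are 0 or
#'   255 only.
#' @return a [WindowSpec-class].
#' @export
windowSpec <- function(huMin = 200, huMax = 3000, format = "png",
                       jpegQuality = 95L, binary = FALSE) {
  new("WindowSpec", huMin = huMin, huMax = huMax, format = format,
      jpegQuality = as.integer(jpegQuality), binary = binary)
}
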