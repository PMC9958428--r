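# DICOM Part-10 writing and Hounsfield-unit conversion.

.encU16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
.encU32 <- function(x) {
  x <- as.numeric(x)
  writeBin(as.integer(ifelse(x > 2147483647, x - 4294967296, x)),
           raw(), size = 4L, endian = "little")
}

.padEven <- function(b, pad = as.raw(0x20)) {
  if (length(b) %% 2L == 1L) c(b, pad) else b
}

.encString <- function(s, ui = FALSE)
  .padEven(charToRaw(s), pad = if (ui) as.raw(0) else as.raw(0x20))

# decimal strings: up to 16 characters per value in the standard; %.10g
# round-trips every geometry value the pipeline writes
.encDS <- function(x) .encString(paste(sprintf("%.10g", x), collapse = "\\"))
.encIS <- function(x) .encString(paste(as.integer(x), collapse = "\\"))
.encUSval <- function(x) {
  x <- as.integer(x)
  writeBin(ifelse(x > 32767L, x - 65536L, x), raw(), size = 2L,
           endian = "little")
}

.element <- function(group, element, vr, bytes)
  list(group = group, element = element, vr = vr, bytes = bytes)

# Serialize one element under explicit or implicit little-endian rules.
.encodeElement <- function(el, explicit) {
  head <- c(.encU16(el$group), .encU16(el$element))
  if (explicit) {
    if (el$vr %in% .LONG_VRS)
      c(head, charToRaw(el$vr), as.raw(c(0, 0)), .encU32(length(el$bytes)),
        el$bytes)
    else
      c(head, charToRaw(el$vr), .encU16(length(el$bytes)), el$bytes)
  } else {
    c(head, .encU32(length(el$bytes)), el$bytes)
  }
}

.serializeElements <- function(elements, explicit) {
  if (!length(elements)) return(raw(0))
  do.call(c, lapply(elements, .encodeElement, explicit = explicit))
}

# File meta group (always explicit LE) with correct group length.
.buildMetaElements <- function(sopInstanceUID, transferSyntax) {
  body <- list(
    .element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .element(0x0002, 0x0002, "UI", .encString(.SOP_CT, ui = TRUE)),
    .element(0x0002, 0x0003, "UI", .encString(sopInstanceUID, ui = TRUE)),
    .element(0x0002, 0x0010, "UI", .encString(transferSyntax, ui = TRUE)),
    .element(0x0002, 0x0012, "UI", .encString(.IMPL_UID, ui = TRUE)))
  groupLen <- length(.serializeElements(body, explicit = TRUE))
  c(list(.element(0x0002, 0x0000, "UL", .encU32(groupLen))), body)
}

.encodePixelBytes <- function(pixels, bitsAllocated, pixelRepresentation) {
  v <- as.integer(t(pixels))               # DICOM pixel order is row-major
  if (bitsAllocated == 16L) {
    .padEven(writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2L,
                      endian = "little"))
  } else {
    .padEven(writeBin(ifelse(v > 127L, v - 256L, v), raw(), size = 1L))
  }
}

# Write a CTSlice back to disk: preserved meta + data elements, pixel data
# re-encoded from the matrix. Atomic: writes a sibling temp file, then renames.
.writeSliceFile <- function(slice, path = slice@sourcePath) {
  explicit <- slice@transferSyntax == .TS_EXPLICIT_LE
  pixEl <- .element(0x7FE0, 0x0010, "OW",
                    .encodePixelBytes(slice@pixels, slice@bitsAllocated,
                                      slice@pixelRepresentation))
  out <- c(raw(128L), charToRaw("DICM"),
           .serializeElements(slice@metaElements, explicit = TRUE),
           .serializeElements(c(slice@elements, list(pixEl)),
                              explicit = explicit))
  tmp <- paste0(path, ".tmp-write")
  con <- file(tmp, "wb")
  writeBin(out, con)
  close(con)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not replace ", path)
  }
  invisible(path)
}

#' Convert stored pixel values to Hounsfield units
#'
#' Applies the per-file linear rescale `HU = stored * slope + intercept`.
#'
#' @param stored integer scalar, vector or matrix of stored values.
#' @param slope HU per stored unit; must be non-zero.
#' @param intercept HU offset.
#' @return numeric of the same shape, in HU.
#' @examples
#' storedToHU(1024, 1, -1024)   # water: 0 HU
#' @export
storedToHU <- function(stored, slope, intercept) {
  stopifnot(slope != 0)
  stored * slope + intercept
}

#' Convert Hounsfield units back to stored pixel values
#'
#' Inverse of [storedToHU()]: rounds `(hu - intercept) / slope` to the
#' nearest integer and clamps it to the representable stored-value range
#' declared by the slice's bit depth and pixel representation (e.g. 0..4095
#' for 12-bit unsigned data).
#'
#' @param hu numeric scalar, vector or matrix of HU values.
#' @param slope,intercept the slice's linear rescale; slope non-zero.
#' @param bitsStored number of stored bits (default 12, typical CT).
#' @param pixelRepresentation 0 for unsigned, 1 for two's-complement signed.
#' @return integer of the same shape, clamped to the stored range.
#' @export
huToStored <- function(hu, slope, intercept, bitsStored = 12L,
                       pixelRepresentation = 0L) {
  stopifnot(slope != 0)
  lo <- if (pixelRepresentation == 1L) -(2^(bitsStored - 1L)) else 0
  hi <- if (pixelRepresentation == 1L) 2^(bitsStored - 1L) - 1 else
    2^bitsStored - 1
  v <- round((hu - intercept) / slope)
  v <- pmin(pmax(v, lo), hi)
  if (is.matrix(hu)) {
    out <- matrix(as.integer(v), nrow = nrow(hu), ncol = ncol(hu))
    out
  } else as.integer(v)
}

#' Overwrite a slice's pixel data in place
#'
#' Replaces the pixel matrix of the file behind a [CTSlice-class] while
#' keeping every other metadata element byte-identical (including matrix
#' dimension attributes, which must therefore match). This is the in-place
#' persistence primitive behind [denoiseSlice()].
#'
#' @param record a [CTSlice-class].
#' @param newPixels integer matrix with the same dimensions as
#'   `pixelData(record)`, in stored units.
#' @return invisibly, the path written.
#' @export
overwritePixels <- function(record, newPixels) {
  stopifnot(is(record, "CTSlice"))
  if (!is.matrix(newPixels) || !all(dim(newPixels) == dim(record@pixels)))
    stop("overwritePixels: new pixel matrix dimensions (",
         paste(dim(newPixels), collapse = "x"),
         ") do not match the slice (",
         paste(dim(record@pixels), collapse = "x"), "); file untouched")
  lo <- if (record@pixelRepresentation == 1L)
    -(2^(record@bitsStored - 1L)) else 0
  hi <- if (record@pixelRepresentation == 1L)
    2^(record@bitsStored - 1L) - 1 else 2^record@bitsStored - 1
  if (min(newPixels) < lo || max(newPixels) > hi)
    stop("overwritePixels: values outside the declared stored range [",
         lo, ", ", hi, "]; file untouched")
  record@pixels <- matrix(as.integer(newPixels), nrow = nrow(newPixels))
  .writeSliceFile(record)
}
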