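# DICOM Part-10 reading: preamble + "DICM" magic, explicit or implicit
# little-endian transfer syntax, uncompressed pixel data. Compressed
# syntaxes, multi-frame enhanced CT and DICOMDIR are out of scope.

.u16 <- function(bytes, at)
  readBin(bytes[at:(at + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")

.u32 <- function(bytes, at) {
  v <- readBin(bytes[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v + 4294967296 else v
}

# Parse a run of data elements in bytes[(at)..(end)]. Returns list(elements,
# next). Errors (treated as corruption by callers) on truncation, undefined
# lengths, or nonsense headers.
.parseElements <- function(bytes, at, end, explicit, stopGroup = NA) {
  elements <- list()
  n <- 0L
  while (at <= end) {
    if (at + 7L > end + 1L) stop("truncated element header")
    group <- .u16(bytes, at)
    element <- .u16(bytes, at + 2L)
    if (!is.na(stopGroup) && group != stopGroup) break
    if (explicit) {
      vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
      if (!grepl("^[A-Z]{2}$", vr)) stop("invalid VR in element header")
      if (vr %in% .LONG_VRS) {
        len <- .u32(bytes, at + 8L)
        valAt <- at + 12L
      } else {
        len <- .u16(bytes, at + 6L)
        valAt <- at + 8L
      }
    } else {
      vr <- .dictVR(group, element)
      len <- .u32(bytes, at + 4L)
      valAt <- at + 8L
    }
    if (len == 4294967295) stop("undefined-length elements not supported")
    if (valAt + len - 1L > end + 1L) stop("element value extends past file end")
    value <- if (len > 0) bytes[valAt:(valAt + len - 1L)] else raw(0)
    n <- n + 1L
    elements[[n]] <- list(group = group, element = element, vr = vr,
                          bytes = value)
    at <- valAt + len
  }
  list(elements = elements, at = at)
}

.decodeString <- function(b) {
  # strip trailing space/nul padding at the byte level (nul is not
  # representable in R character literals)
  while (length(b) && b[length(b)] %in% as.raw(c(0x00, 0x20)))
    b <- b[-length(b)]
  rawToChar(b)
}

.decodeElementValue <- function(el) {
  b <- el$bytes
  switch(el$vr,
    US = readBin(b, "integer", n = length(b) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(b, "integer", n = length(b) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = .u32(b, 1L),
    FL = readBin(b, "double", n = length(b) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(b, "double", n = length(b) / 8L, endian = "little"),
    DS = as.numeric(strsplit(.decodeString(b), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(.decodeString(b), "\\", fixed = TRUE)[[1]]),
    if (el$vr %in% .STRING_VRS) .decodeString(b) else b)
}

# Full Part-10 parse: returns list(meta, data, transferSyntax). The file meta
# group is always explicit little-endian; the main data set follows the
# transfer syntax it declares.
.parseDicomFile <- function(path) {
  size <- file.size(path)
  bytes <- readBin(path, "raw", n = size)
  if (size < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("no DICOM format signature")
  meta <- .parseElements(bytes, 133L, size, explicit = TRUE, stopGroup = 2L)
  tsEl <- Filter(function(e) e$element == 0x0010, meta$elements)
  if (!length(tsEl)) stop("file meta lacks a transfer syntax UID")
  ts <- .decodeString(tsEl[[1]]$bytes)
  explicit <- ts == .TS_EXPLICIT_LE
  if (!explicit && ts != .TS_IMPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  data <- .parseElements(bytes, meta$at, size, explicit = explicit)
  list(meta = meta$elements, data = data$elements, transferSyntax = ts)
}

.findElement <- function(elements, group, element) {
  for (el in elements)
    if (el$group == group && el$element == element) return(el)
  NULL
}

.requireValue <- function(elements, group, element, what, n = NULL) {
  el <- .findElement(elements, group, element)
  if (is.null(el)) stop("missing required attribute: ", what)
  v <- .decodeElementValue(el)
  if (!is.null(n) && length(v) != n)
    stop(what, " must have ", n, " value(s)")
  if (is.character(v) && !is.null(n) && !all(nzchar(v)))
    stop(what, " is empty")
  v
}

.readSliceImpl <- function(path) {
  parsed <- .parseDicomFile(path)
  d <- parsed$data
  rows <- .requireValue(d, 0x0028, 0x0010, "Rows", 1L)
  cols <- .requireValue(d, 0x0028, 0x0011, "Columns", 1L)
  slope <- .requireValue(d, 0x0028, 0x1053, "RescaleSlope", 1L)
  intercept <- .requireValue(d, 0x0028, 0x1052, "RescaleIntercept", 1L)
  spacing <- .requireValue(d, 0x0028, 0x0030, "PixelSpacing", 2L)
  pos <- .requireValue(d, 0x0020, 0x0032, "ImagePositionPatient", 3L)
  orient <- .requireValue(d, 0x0020, 0x0037, "ImageOrientationPatient", 6L)
  if (anyNA(c(rows, cols, slope, intercept, spacing, pos, orient)))
    stop("undecodable numeric geometry/rescale attribute")

  serEl <- .findElement(d, 0x0020, 0x0011)
  seriesNumber <- if (is.null(serEl)) NA_integer_ else
    as.integer(.decodeElementValue(serEl))
  uidEl <- .findElement(d, 0x0020, 0x000E)
  seriesUID <- if (is.null(uidEl)) "" else .decodeElementValue(uidEl)
  if (is.na(seriesNumber) && !nzchar(seriesUID))
    stop("missing required attribute: SeriesNumber or SeriesInstanceUID")
  instEl <- .findElement(d, 0x0020, 0x0013)
  instanceNumber <- if (is.null(instEl)) NA_integer_ else
    as.integer(.decodeElementValue(instEl))
  thickEl <- .findElement(d, 0x0018, 0x0050)
  thickness <- if (is.null(thickEl)) NA_real_ else
    .decodeElementValue(thickEl)

  bitsAlloc <- .findElement(d, 0x0028, 0x0100)
  bitsAlloc <- if (is.null(bitsAlloc)) 16L else
    as.integer(.decodeElementValue(bitsAlloc))
  if (!bitsAlloc %in% c(8L, 16L))
    stop("unsupported BitsAllocated: ", bitsAlloc)
  bitsStored <- .findElement(d, 0x0028, 0x0101)
  bitsStored <- if (is.null(bitsStored)) bitsAlloc else
    as.integer(.decodeElementValue(bitsStored))
  pixRep <- .findElement(d, 0x0028, 0x0103)
  pixRep <- if (is.null(pixRep)) 0L else
    as.integer(.decodeElementValue(pixRep))

  pixEl <- .findElement(d, 0x7FE0, 0x0010)
  if (is.null(pixEl)) stop("missing required attribute: PixelData")
  bytesPer <- bitsAlloc / 8L
  need <- as.numeric(rows) * cols * bytesPer
  if (length(pixEl$bytes) < need)
    stop("pixel data shorter than Rows x Columns x BitsAllocated/8")
  vals <- readBin(pixEl$bytes, "integer", n = rows * cols, size = bytesPer,
                  signed = pixRep == 1L, endian = "little")
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  dataKeep <- Filter(function(e) !(e$group == 0x7FE0 && e$element == 0x0010),
                     d)
  obj <- new("CTSlice",
    pixels = pixels,
    rescaleSlope = as.numeric(slope),
    rescaleIntercept = as.numeric(intercept),
    pixelSpacing = as.numeric(spacing),
    sliceThickness = as.numeric(thickness),
    imagePosition = as.numeric(pos),
    imageOrientation = matrix(as.numeric(orient), nrow = 3L, ncol = 2L),
    seriesNumber = seriesNumber, seriesUID = seriesUID,
    instanceNumber = instanceNumber,
    bitsAllocated = bitsAlloc, bitsStored = bitsStored,
    pixelRepresentation = pixRep,
    transferSyntax = parsed$transferSyntax,
    sourcePath = normalizePath(path),
    metaElements = parsed$meta, elements = dataKeep)
  validObject(obj)
  obj
}

#' Classify a candidate input file
#'
#' Decides whether a file is a usable DICOM slice. `valid` means the file
#' parses fully and carries a decodable pixel matrix plus every geometry and
#' rescale attribute the pipeline needs; `non_dicom` means the Part-10
#' format signature (128-byte preamble + `DICM`) is absent; `corrupted`
#' means the signature is present but parsing, attribute decoding or pixel
#' decoding fails.
#'
#' @param path path to an existing regular file.
#' @return a [FileClassification-class].
#' @examples
#' tmp <- tempfile(); writeLines("not an image", tmp)
#' classifyFile(tmp)
#' @export
classifyFile <- function(path) {
  if (length(path) != 1L || !file.exists(path) || dir.exists(path))
    stop("classifyFile: no such file: ", path)
  size <- file.size(path)
  if (size < 132L)
    return(new("FileClassification", status = "non_dicom",
               detail = "file shorter than DICOM preamble"))
  sig <- readBin(path, "raw", n = 132L)
  if (rawToChar(sig[129:132]) != "DICM")
    return(new("FileClassification", status = "non_dicom",
               detail = "no DICM format signature"))
  res <- tryCatch(.readSliceImpl(path), error = function(e) e)
  if (inherits(res, "error"))
    return(new("FileClassification", status = "corrupted",
               detail = conditionMessage(res)))
  new("FileClassification", status = "valid", detail = "")
}

#' Read one DICOM slice
#'
#' Decodes a valid DICOM file into a [CTSlice-class]. All metadata elements
#' not mapped to a named slot are preserved verbatim for round-tripping; see
#' [extraTags()].
#'
#' @param path path to a valid DICOM file (see [classifyFile()]).
#' @return a [CTSlice-class].
#' @export
readSlice <- function(path) {
  if (length(path) != 1L || !file.exists(path))
    stop("readSlice: no such file: ", path)
  tryCatch(.readSliceImpl(path), error = function(e) {
    cls <- classifyFile(path)
    stop("readSlice: file is ", cls@status, ": ", cls@detail,
         call. = FALSE)
  })
}
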