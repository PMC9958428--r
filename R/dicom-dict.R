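# Minimal DICOM data dictionary: the tags the pipeline interprets, plus VR
# lookup for decoding implicit-VR files. Everything else is carried as raw
# bytes with VR "UN".

.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
# registered-style implementation UID root used for generated files
.IMPL_UID <- "2.25.424242424242424242424242"

.tagKey <- function(group, element) sprintf("%04X%04X", group, element)

.DICT <- local({
  d <- list(
    list(0x0002, 0x0000, "UL", "FileMetaInformationGroupLength"),
    list(0x0002, 0x0001, "OB", "FileMetaInformationVersion"),
    list(0x0002, 0x0002, "UI", "MediaStorageSOPClassUID"),
    list(0x0002, 0x0003, "UI", "MediaStorageSOPInstanceUID"),
    list(0x0002, 0x0010, "UI", "TransferSyntaxUID"),
    list(0x0002, 0x0012, "UI", "ImplementationClassUID"),
    list(0x0008, 0x0016, "UI", "SOPClassUID"),
    list(0x0008, 0x0018, "UI", "SOPInstanceUID"),
    list(0x0008, 0x0020, "DA", "StudyDate"),
    list(0x0008, 0x0021, "DA", "SeriesDate"),
    list(0x0008, 0x0060, "CS", "Modality"),
    list(0x0010, 0x0010, "PN", "PatientName"),
    list(0x0010, 0x0020, "LO", "PatientID"),
    list(0x0010, 0x0040, "CS", "PatientSex"),
    list(0x0010, 0x1010, "AS", "PatientAge"),
    list(0x0018, 0x0050, "DS", "SliceThickness"),
    list(0x0018, 0x0060, "DS", "KVP"),
    list(0x0020, 0x000D, "UI", "StudyInstanceUID"),
    list(0x0020, 0x000E, "UI", "SeriesInstanceUID"),
    list(0x0020, 0x0011, "IS", "SeriesNumber"),
    list(0x0020, 0x0013, "IS", "InstanceNumber"),
    list(0x0020, 0x0032, "DS", "ImagePositionPatient"),
    list(0x0020, 0x0037, "DS", "ImageOrientationPatient"),
    list(0x0028, 0x0002, "US", "SamplesPerPixel"),
    list(0x0028, 0x0004, "CS", "PhotometricInterpretation"),
    list(0x0028, 0x0010, "US", "Rows"),
    list(0x0028, 0x0011, "US", "Columns"),
    list(0x0028, 0x0030, "DS", "PixelSpacing"),
    list(0x0028, 0x0100, "US", "BitsAllocated"),
    list(0x0028, 0x0101, "US", "BitsStored"),
    list(0x0028, 0x0102, "US", "HighBit"),
    list(0x0028, 0x0103, "US", "PixelRepresentation"),
    list(0x0028, 0x1052, "DS", "RescaleIntercept"),
    list(0x0028, 0x1053, "DS", "RescaleSlope"),
    list(0x7FE0, 0x0010, "OW", "PixelData"))
  keys <- vapply(d, function(e) .tagKey(e[[1]], e[[2]]), "")
  names(d) <- keys
  d
})

.DICT_BY_NAME <- local({
  nm <- vapply(.DICT, function(e) e[[4]], "")
  keys <- names(.DICT)
  names(keys) <- nm
  keys
})

.dictVR <- function(group, element) {
  e <- .DICT[[.tagKey(group, element)]]
  if (is.null(e)) "UN" else e[[3]]
}

.dictName <- function(group, element) {
  e <- .DICT[[.tagKey(group, element)]]
  if (is.null(e)) NA_character_ else e[[4]]
}

# VRs that use the 12-byte (long) explicit header
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
# string-like VRs decoded to character
.STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                 "ST", "TM", "UI", "UT")
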