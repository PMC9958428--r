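# DICOM decoding, Hounsfield rescale, in-place pixel overwrite.

test_that("Hounsfield rescale is the declared linear map and its inverse", {
  expect_equal(storedToHU(1024, 1.0, -1024), 0)
  expect_equal(storedToHU(0, 1.0, -1024), -1024)
  expect_equal(storedToHU(500, 2.0, -1000), 0)
  expect_error(storedToHU(1, 0, 0))

  expect_identical(huToStored(0, 1.0, -1024), 1024L)
  # mutual inverses on in-range integers at slope 1
  stored <- c(0L, 1L, 37L, 2048L, 4095L)
  expect_identical(huToStored(storedToHU(stored, 1, -1024), 1, -1024),
                   stored)
  # clamping against an explicit oracle across representations
  clampOracle <- function(hu, bits, rep) {
    lo <- if (rep == 1L) -2^(bits - 1) else 0
    hi <- if (rep == 1L) 2^(bits - 1) - 1 else 2^bits - 1
    as.integer(pmin(pmax(round(hu + 1024), lo), hi))
  }
  hus <- c(-5000, -1024.4, -1023.5, 0, 3070.6, 3071, 9000)
  for (bits in c(12L, 16L)) for (rep in c(0L, 1L))
    expect_identical(huToStored(hus, 1, -1024, bits, rep),
                     clampOracle(hus, bits, rep),
                     info = paste("bits", bits, "rep", rep))
})

test_that("file classification separates valid, non-DICOM and corrupted", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 11L), d)
  valid <- list.files(d, pattern = "^IM", full.names = TRUE)

  expect_s4_class(classifyFile(valid[1]), "FileClassification")
  expect_identical(classifyFile(valid[1])@status, "valid")

  txt <- file.path(d, "notes.txt")
  writeLines(strrep("plain text, much longer than a DICOM preamble. ", 20),
             txt)
  expect_identical(classifyFile(txt)@status, "non_dicom")

  # truncation to half length: signature survives, parsing cannot
  half <- file.path(d, "broken.dcm")
  bytes <- readBin(valid[1], "raw", n = file.size(valid[1]))
  writeBin(bytes[seq_len(length(bytes) %/% 2L)], half)
  cls <- classifyFile(half)
  expect_identical(cls@status, "corrupted")
  expect_true(nzchar(cls@detail))

  expect_error(classifyFile(file.path(d, "absent.dcm")), "no such file")

  # totality: every file in the mixed directory gets exactly one status
  statuses <- vapply(list.files(d, full.names = TRUE),
                     function(f) classifyFile(f)@status, "")
  expect_true(all(statuses %in% c("valid", "non_dicom", "corrupted")))
})

test_that("a slice reads back the metadata the generator wrote", {
  d <- newStudyDir()
  spec <- smallPhantomSpec(nSlices = 3L, seed = 5L)
  makePhantomStudy(spec, d)
  s <- readSlice(file.path(d, "IM000002.dcm"))
  expect_identical(seriesNumber(s), 1L)
  expect_identical(instanceNumber(s), 2L)
  expect_identical(pixelSpacing(s), c(0.5, 0.5))
  expect_identical(sliceThickness(s), 0.5)
  expect_identical(rescaleSlope(s), 1)
  expect_identical(rescaleIntercept(s), -1024)
  expect_identical(dim(s), c(128L, 128L))
  expect_equal(imagePosition(s), c(-31.75, -31.75, 0.5))
  expect_equal(imageOrientation(s), matrix(c(1, 0, 0, 0, 1, 0), 3, 2))
  # non-named attributes are preserved and decodable
  tags <- extraTags(s)
  expect_identical(tags[["00080060"]], "CT")
  expect_identical(tags[["00100040"]], "O")
})

test_that("read -> write -> read round-trips byte-for-byte", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 2L), d)
  f <- file.path(d, "IM000001.dcm")
  before <- readBin(f, "raw", n = file.size(f))
  s <- readSlice(f)
  overwritePixels(s, pixelData(s))
  after <- readBin(f, "raw", n = file.size(f))
  expect_identical(before, after)

  s2 <- readSlice(f)
  expect_identical(pixelData(s2), pixelData(s))
  expect_identical(s2@elements, s@elements)
  expect_identical(s2@metaElements, s@metaElements)
})

test_that("overwrite validates dimensions and leaves the file intact", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 1L, seed = 3L), d)
  f <- file.path(d, "IM000001.dcm")
  s <- readSlice(f)
  before <- readBin(f, "raw", n = file.size(f))
  expect_error(overwritePixels(s, matrix(0L, 64L, 64L)),
               "dimensions.*do not match")
  expect_error(overwritePixels(s, matrix(99999L, 128L, 128L)),
               "stored range")
  expect_identical(readBin(f, "raw", n = file.size(f)), before)

  # a real overwrite persists the new matrix, all metadata unchanged
  fpBefore <- elementFingerprint(f)
  newPix <- matrix(7L, 128L, 128L)
  overwritePixels(s, newPix)
  s2 <- readSlice(f)
  expect_identical(pixelData(s2), newPix)
  expect_identical(elementFingerprint(f), fpBefore)
})

test_that("pydicom independently agrees with the reader and writer", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 1L, seed = 13L), d)
  f <- file.path(d, "IM000001.dcm")
  s <- readSlice(f)
  code <- paste(
    "import pydicom, json, numpy as np",
    sprintf("ds = pydicom.dcmread(r'%s')", f),
    "a = ds.pixel_array",
    "print(json.dumps({'rows': int(ds.Rows), 'cols': int(ds.Columns),",
    " 'series': int(ds.SeriesNumber), 'instance': int(ds.InstanceNumber),",
    " 'slope': float(ds.RescaleSlope), 'intercept': float(ds.RescaleIntercept),",
    " 'spacing': [float(x) for x in ds.PixelSpacing],",
    " 'pos': [float(x) for x in ds.ImagePositionPatient],",
    " 'uid': str(ds.SeriesInstanceUID),",
    " 'pixsum': int(a.sum()), 'pix00': int(a[0,0]), 'pix_5_7': int(a[4,6])}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_identical(ref$rows, nrow(pixelData(s)))
  expect_identical(ref$series, seriesNumber(s))
  expect_identical(ref$instance, instanceNumber(s))
  expect_equal(ref$slope, rescaleSlope(s))
  expect_equal(ref$intercept, rescaleIntercept(s))
  expect_equal(ref$spacing, pixelSpacing(s))
  expect_equal(ref$pos, imagePosition(s))
  expect_identical(ref$uid, seriesUID(s))
  expect_identical(ref$pixsum, sum(pixelData(s)))
  expect_identical(ref$pix00, pixelData(s)[1, 1])
  expect_identical(ref$pix_5_7, pixelData(s)[5, 7])
})
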