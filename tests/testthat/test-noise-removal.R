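# Patient masking and in-place couch/noise removal.

test_that("tissue thresholding is an elementwise band test", {
  spec <- thresholdSpec()
  expect_false(any(tissueThreshold(matrix(-1000, 4, 4), spec)))
  full <- thresholdSpec(tissueLower = -2000, tissueUpper = 4000)
  expect_true(all(tissueThreshold(matrix(c(-1000, 0, 700, 3000), 2), full)))
  m <- matrix(c(-301, -300, 3000, 3001), 2)
  expect_identical(as.vector(tissueThreshold(m, spec)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("the patient mask keeps the largest component and fills holes", {
  # disk (~2000 px) plus a thin arc (~300 px): area-ranked selection
  n <- 101L
  xy <- (seq_len(n) - 51)
  X <- matrix(xy, n, n, byrow = TRUE); Y <- t(X)
  disk <- X^2 + Y^2 < 25^2
  arc <- abs(sqrt(X^2 + Y^2) - 45) < 1.6 & Y > 30
  expect_gt(sum(disk), 1900); expect_gt(sum(arc), 100)
  mask <- buildPatientMask(disk | arc)
  expect_true(all(maskMatrix(mask)[disk]))
  expect_false(any(maskMatrix(mask)[arc]))

  # all-false input: degenerate, flagged, not an error
  empty <- buildPatientMask(matrix(FALSE, 8, 8))
  expect_false(any(maskMatrix(empty)))
  expect_true(provenance(empty)$empty)

  # annulus (body wall around an air hole): flood-fillable hole is filled
  ring <- X^2 + Y^2 < 30^2 & X^2 + Y^2 > 15^2
  filled <- maskMatrix(buildPatientMask(ring))
  expect_true(all(filled[X^2 + Y^2 < 28^2]))
})

test_that("masking zeroes stored pixels outside the mask only", {
  d <- newStudyDir()
  spec <- smallPhantomSpec(nSlices = 1L, seed = 31L)
  makePhantomStudy(spec, d)
  s <- readSlice(file.path(d, "IM000001.dcm"))

  allTrue <- matrix(TRUE, 128, 128)
  expect_identical(applyMask(s, allTrue), pixelData(s))
  expect_true(all(applyMask(s, !allTrue) == 0L))
  expect_error(applyMask(s, matrix(TRUE, 64, 64)), "dimensions")

  truth <- groundTruthMasks(spec)
  mask <- buildPatientMask(tissueThreshold(huMatrix(s), thresholdSpec()))
  out <- applyMask(s, mask)
  expect_true(all(out[truth$table[, , 1]] == 0L))
  # body interior untouched (the one-pixel partial-volume rim at the body
  # edge straddles the tissue threshold and belongs to neither side)
  interior <- EBImage::erode(truth$body[, , 1] * 1,
                             EBImage::makeBrush(5, "disc")) > 0
  expect_identical(out[interior], pixelData(s)[interior])
})

test_that("denoising removes the couch, keeps the body, preserves metadata", {
  d <- newStudyDir()
  spec <- smallPhantomSpec(nSlices = 1L, seed = 32L, noiseSD = 10)
  makePhantomStudy(spec, d)
  f <- file.path(d, "IM000001.dcm")
  truth <- groundTruthMasks(spec)
  fpBefore <- elementFingerprint(f)

  r <- denoiseSlice(f)
  expect_identical(r$status, "denoised")
  hu <- huMatrix(readSlice(f))
  # every ground-truth couch pixel is at background
  expect_true(all(hu[truth$table[, , 1]] == -1024))
  # body recovered at high fidelity
  rec <- hu > -1024
  expect_gte(diceCoefficient(rec, truth$body[, , 1]), 0.99)
  # metadata diff: zero changes
  expect_identical(elementFingerprint(f), fpBefore)
  # matrix size preserved
  expect_identical(dim(readSlice(f)), c(128L, 128L))
})

test_that("denoising twice leaves the pixel payload byte-identical", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 33L, noiseSD = 15),
                   d)
  for (f in list.files(d, full.names = TRUE)) {
    denoiseSlice(f)
    once <- readBin(f, "raw", n = file.size(f))
    denoiseSlice(f)
    expect_identical(readBin(f, "raw", n = file.size(f)), once)
  }
})

test_that("body recovery stays above Dice 0.99 for noise up to 20 HU", {
  for (sd in c(0, 10, 20)) {
    d <- newStudyDir()
    spec <- smallPhantomSpec(nSlices = 2L, seed = 34L + sd, noiseSD = sd)
    makePhantomStudy(spec, d)
    truth <- groundTruthMasks(spec)
    for (k in 1:2) {
      f <- file.path(d, sprintf("IM%06d.dcm", k))
      denoiseSlice(f)
      rec <- huMatrix(readSlice(f)) > -1024
      expect_gte(diceCoefficient(rec, truth$body[, , k]), 0.99)
    }
  }
})

test_that("series denoising reports per file and guards mixed series", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 3L, nSeries = 2L, seed = 35L),
                   d)
  sortStudy(d)
  rep <- denoiseSeries(file.path(d, "1"))
  expect_identical(nrow(rep), 3L)
  expect_true(all(rep$status == "denoised"))

  empty <- newStudyDir()
  expect_identical(nrow(denoiseSeries(empty)), 0L)

  mixed <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, nSeries = 2L, seed = 36L),
                   mixed)
  before <- lapply(list.files(mixed, full.names = TRUE), function(f)
    readBin(f, "raw", n = file.size(f)))
  expect_error(denoiseSeries(mixed), "mixes 2 series")
  after <- lapply(list.files(mixed, full.names = TRUE), function(f)
    readBin(f, "raw", n = file.size(f)))
  expect_identical(after, before)        # error before modification
})

test_that("per-slice and volumetric masking agree when the couch is 3-D disconnected", {
  mkStudy <- function(seed) {
    d <- newStudyDir()
    makePhantomStudy(smallPhantomSpec(nSlices = 4L, seed = seed,
                                      noiseSD = 5), d)
    sortStudy(d)
    file.path(d, "1")
  }
  s1 <- mkStudy(37L); s2 <- mkStudy(37L)
  denoiseSeries(s1, mode = "slice")
  denoiseSeries(s2, mode = "volume")
  for (k in 1:4) {
    f1 <- file.path(s1, sprintf("IM%06d.dcm", k))
    f2 <- file.path(s2, sprintf("IM%06d.dcm", k))
    expect_identical(pixelData(readSlice(f1)), pixelData(readSlice(f2)))
  }
})
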