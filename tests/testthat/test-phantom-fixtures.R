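# The synthetic study generator itself.

test_that("a study contains nSeries x nSlices valid files plus decoys", {
  d <- newStudyDir()
  spec <- smallPhantomSpec(nSlices = 4L, nSeries = 2L, seed = 71L,
                           decoyNonDicom = 2L, decoyCorrupted = 1L)
  mf <- makePhantomStudy(spec, d)
  expect_identical(sum(mf$kind == "slice"), 8L)
  expect_identical(nrow(mf), 11L)
  expect_length(list.files(d), 11L)
  # every emitted slice is valid; every decoy fails as intended
  for (i in seq_len(nrow(mf))) {
    status <- classifyFile(mf$path[i])@status
    expected <- c(slice = "valid", decoy_non_dicom = "non_dicom",
                  decoy_corrupted = "corrupted")[[mf$kind[i]]]
    expect_identical(status, expected, info = mf$path[i])
  }
})

test_that("the same seed reproduces a study byte for byte", {
  spec <- smallPhantomSpec(nSlices = 2L, nSeries = 2L, seed = 72L,
                           noiseSD = 12, decoyCorrupted = 1L)
  d1 <- newStudyDir(); d2 <- newStudyDir()
  makePhantomStudy(spec, d1)
  makePhantomStudy(spec, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", n = file.size(f1[i])),
                     readBin(f2[i], "raw", n = file.size(f2[i])))
  # a different seed changes the noise realisation
  d3 <- newStudyDir()
  spec2 <- smallPhantomSpec(nSlices = 2L, nSeries = 2L, seed = 73L,
                            noiseSD = 12, decoyCorrupted = 1L)
  makePhantomStudy(spec2, d3)
  f3 <- list.files(d3, full.names = TRUE)[1]
  expect_false(identical(pixelData(readSlice(f1[1])),
                         pixelData(readSlice(f3))))
})

test_that("at zero noise the stored values are the quantised material HUs", {
  d <- newStudyDir()
  # one sphere spanning the whole sampled z-range, so no insert presents a
  # between-slice end cap whose partial volume would blur a sampled slice
  spec <- smallPhantomSpec(nSlices = 2L, seed = 74L, noiseSD = 0,
                           boneInserts = list(
                             list(type = "sphere", center = c(8, 0, 0.5),
                                  radius = 4)))
  makePhantomStudy(spec, d)
  truth <- groundTruthMasks(spec)
  s <- readSlice(file.path(d, "IM000001.dcm"))
  hu <- huMatrix(s)
  # interiors (eroded away from partial-volume edges) are exact plateaus
  erode <- function(m) {
    k <- EBImage::makeBrush(5, "disc")
    EBImage::erode(m * 1, k) > 0
  }
  dilate <- function(m) {
    k <- EBImage::makeBrush(5, "disc")
    EBImage::dilate(m * 1, k) > 0
  }
  bodyCore <- erode(truth$body[, , 1]) & !dilate(truth$bone[, , 1])
  boneCore <- erode(truth$bone[, , 1])
  tabCore <- erode(truth$table[, , 1])
  airCore <- !(truth$body[, , 1] | truth$table[, , 1] | truth$bone[, , 1])
  airCore <- erode(airCore)
  expect_true(all(hu[boneCore] == 700))
  expect_true(all(hu[bodyCore & !boneCore] == 40))
  expect_true(all(hu[tabCore] == 150))
  expect_true(all(hu[airCore] == -1000))
})

test_that("ground-truth masks obey the geometric containment relations", {
  spec <- smallPhantomSpec(nSlices = 3L, seed = 75L)
  truth <- groundTruthMasks(spec)
  # disjoint body and table; bone inside body
  expect_false(any(truth$body & truth$table))
  expect_true(all(truth$body[truth$bone]))
  # body pixel count matches the analytic ellipse area at grid resolution
  pxArea <- sum(truth$body[, , 1]) * 0.5^2
  expect_lt(abs(pxArea / (pi * 20 * 15) - 1), 0.02)
  # a slice beyond all inserts has no bone (sphere/cylinder span z mid)
  spec2 <- smallPhantomSpec(nSlices = 8L, seed = 75L, boneInserts = list(
    list(type = "sphere", center = c(8, 0, 1), radius = 0.9)))
  truth2 <- groundTruthMasks(spec2)
  expect_false(any(truth2$bone[, , 8]))
  expect_true(any(truth2$bone[, , 3]))
})

test_that("overlapping body and table specs are rejected", {
  expect_error(
    phantomSpec(matrixSize = 64L, bodySemiAxes = c(30, 25),
                tableRadius = 30, tableWidth = 4),
    "overlaps")
})

test_that("truth bundle is written as NIfTI masks plus a JSON manifest", {
  d <- newStudyDir(); td <- tempfile("truth")
  spec <- smallPhantomSpec(nSlices = 2L, seed = 76L)
  makePhantomStudy(spec, d, truthDir = td)
  expect_setequal(list.files(td),
                  c("truth_body.nii", "truth_table.nii", "truth_bone.nii",
                    "truth_manifest.json"))
  body <- RNifti::readNifti(file.path(td, "truth_body.nii"))
  truth <- groundTruthMasks(spec)
  expect_identical(array(as.integer(body), dim(body)),
                   array(as.integer(truth$body), dim(truth$body)))
  man <- jsonlite::fromJSON(file.path(td, "truth_manifest.json"))
  expect_identical(man$seed, 76L)
  expect_identical(man$nSlices, 2L)
})
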