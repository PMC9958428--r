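# Study restructuring: purge, per-series sorting, metadata-based deletion.

test_that("purge reports and removes exactly the invalid files", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 5L, nSeries = 2L, seed = 21L,
                                    decoyNonDicom = 1L,
                                    decoyCorrupted = 1L), d)
  # 10 valid + 2 decoys by construction
  rep1 <- purgeInvalid(d, delete = FALSE)
  expect_identical(nrow(rep1), 2L)
  expect_setequal(rep1$status, c("non_dicom", "corrupted"))
  expect_length(list.files(d), 12L)

  rep2 <- purgeInvalid(d, delete = TRUE)
  expect_identical(nrow(rep2), 2L)
  expect_length(list.files(d), 10L)
  expect_identical(nrow(purgeInvalid(d)), 0L)

  empty <- newStudyDir()
  expect_identical(nrow(purgeInvalid(empty)), 0L)
  expect_error(purgeInvalid(file.path(d, "nope")), "directory")
})

test_that("sorting groups files by series with conserved counts", {
  d <- newStudyDir()
  # 2 series x 3 slices, interleaved on disk
  makePhantomStudy(smallPhantomSpec(nSlices = 3L, nSeries = 2L, seed = 22L),
                   d)
  nBefore <- length(list.files(d))
  idx <- sortStudy(d)
  expect_s4_class(idx, "SeriesIndex")
  expect_setequal(names(idx@index), c("1", "2"))
  expect_identical(lengths(idx@index), c(`1` = 3L, `2` = 3L))
  # conservation: nothing lost or duplicated
  after <- list.files(d, recursive = TRUE)
  after <- after[basename(after) != "series_index.json"]
  expect_length(after, nBefore)
  expect_true(all(file.exists(unlist(idx@index))))
  # layout contract: <study>/<series number>/<original filename>
  expect_true(all(dirname(unlist(idx@index)) %in% file.path(d, c("1", "2"))))
  # index JSON written
  expect_true(file.exists(file.path(d, "series_index.json")))
})

test_that("within a series the index is ordered by instance number", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 3L, seed = 23L), d)
  # shuffle listing order via renames: IM1->z, IM3->a
  file.rename(file.path(d, "IM000001.dcm"), file.path(d, "z.dcm"))
  file.rename(file.path(d, "IM000003.dcm"), file.path(d, "a.dcm"))
  idx <- sortStudy(d)
  inst <- vapply(idx@index[["1"]],
                 function(f) instanceNumber(readSlice(f)), 1L)
  expect_identical(unname(inst), c(1L, 2L, 3L))
})

test_that("sorting is idempotent and deterministic", {
  mk <- function() {
    d <- newStudyDir()
    makePhantomStudy(smallPhantomSpec(nSlices = 2L, nSeries = 2L,
                                      seed = 24L), d)
    d
  }
  d1 <- mk()
  idx1 <- sortStudy(d1)
  tree1 <- list.files(d1, recursive = TRUE)
  idx1b <- sortStudy(d1)                     # already sorted: no-op
  expect_identical(list.files(d1, recursive = TRUE), tree1)
  expect_identical(lapply(idx1b@index, basename),
                   lapply(idx1@index, basename))

  d2 <- mk()                                 # identical input tree
  idx2 <- sortStudy(d2)
  expect_identical(list.files(d2, recursive = TRUE), tree1)
  expect_identical(names(idx2@index), names(idx1@index))
})

test_that("distinct UIDs sharing a series number get suffixed subfolders", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 25L), d)
  other <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 26L), other)
  for (f in list.files(other, full.names = TRUE))
    file.rename(f, file.path(d, paste0("b_", basename(f))))
  idx <- sortStudy(d)
  expect_setequal(names(idx@index), c("1", "1-2"))
  expect_identical(idx@collisions, "1-2")
  expect_identical(unname(lengths(idx@index)), c(2L, 2L))
})

test_that("single-file study yields one subfolder named by its series", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 1L, seed = 27L), d)
  idx <- sortStudy(d)
  expect_identical(names(idx@index), "1")
  expect_length(idx@index[["1"]], 1L)
})

test_that("metadata predicates delete matching files and skip unresolvable ones", {
  d <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 6L, seed = 28L), d)
  thick <- newStudyDir()
  makePhantomStudy(phantomSpec(matrixSize = 64L, nSlices = 4L,
                               pixelSpacing = 1, sliceThickness = 2,
                               bodySemiAxes = c(20, 15), tableRadius = 27,
                               tableWidth = 3, seed = 29L,
                               boneInserts = list()), thick)
  for (f in list.files(thick, full.names = TRUE))
    file.rename(f, file.path(d, paste0("t_", basename(f))))
  # 4 of 10 files have thickness 2.0 mm: the filter oracle by construction
  res <- deleteByMetadata(d, "slice_thickness", ">", 1.0)
  expect_length(res$deleted, 4L)
  expect_length(list.files(d), 6L)
  expect_true(all(startsWith(basename(res$deleted), "t_")))

  # matching nothing: no change
  res2 <- deleteByMetadata(d, "series_number", "==", 999L)
  expect_length(res2$deleted, 0L)
  expect_length(list.files(d), 6L)

  # absent attribute: everything skipped, nothing deleted
  res3 <- deleteByMetadata(d, "00081030", "==", "x")
  expect_length(res3$deleted, 0L)
  expect_length(res3$skipped, 6L)

  # malformed predicate: error before any deletion
  expect_error(deleteByMetadata(d, "slice_thickness", "~=", 1),
               "malformed predicate")
  expect_length(list.files(d), 6L)
})
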