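# Isosurface extraction and STL writing.

test_that("fields without an iso crossing give an empty mesh", {
  vox <- array(-1000, c(4, 4, 4))
  aff <- diag(c(1, 1, 1, 1))
  vol <- new("CTVolume", voxels = vox, affine = aff, spacing = c(1, 1, 1))
  m <- extractIsosurface(vol, 200)
  expect_identical(nrow(triangles(m)), 0L)
  # iso below the global minimum: also empty
  expect_identical(nrow(triangles(extractIsosurface(vol, -2000))), 0L)
})

test_that("sphere mesh is closed with accurate, converging surface area", {
  areas <- c()
  for (sp in c(0.5, 0.25)) {
    vol <- sphereVolume(radius = 10, spacing = sp, insideHU = 700,
                        outsideHU = -1000, iso = 200, edgeWidth = 1)
    m <- extractIsosurface(vol, 200)
    # watertight: every edge shared by exactly two triangles
    expect_true(all(meshEdgeUse(m) == 2L))
    # closed surface of genus 0
    expect_identical(eulerCharacteristic(m), 2L)
    expect_identical(meshComponentCount(m), 1L)
    areas <- c(areas, meshArea(m))
  }
  true <- 4 * pi * 100
  expect_lt(abs(areas[1] / true - 1), 0.02)
  # refinement reduces the area error
  expect_lt(abs(areas[2] / true - 1), abs(areas[1] / true - 1))
})

test_that("enclosed mesh volume matches the analytic sphere within 3%", {
  vol <- sphereVolume(radius = 10, spacing = 0.25)
  m <- extractIsosurface(vol, 200)
  expect_lt(abs(meshVolume(m) / (4 / 3 * pi * 1000) - 1), 0.03)
  # outward winding: positive divergence-theorem volume
  expect_gt(meshVolume(m), 0)
})

test_that("a single interior voxel above iso encloses one component", {
  vox <- array(-1000, c(5, 5, 5))
  vox[3, 3, 3] <- 700
  vol <- new("CTVolume", voxels = vox, affine = diag(4),
             spacing = c(1, 1, 1))
  m <- extractIsosurface(vol, 200)
  expect_gt(nrow(triangles(m)), 0L)
  expect_identical(meshComponentCount(m), 1L)
  expect_true(all(meshEdgeUse(m) == 2L))
  expect_identical(eulerCharacteristic(m), 2L)
  # it encloses the voxel's neighbourhood: positive volume
  expect_gt(meshVolume(m), 0)
})

test_that("mesh invariants hold: indices in range, no degenerate facets, unit normals", {
  vol <- sphereVolume(radius = 6, spacing = 0.5)
  m <- extractIsosurface(vol, 200)
  tri <- triangles(m); V <- vertices(m)
  expect_true(all(tri >= 1L & tri <= nrow(V)))
  e1 <- V[tri[, 2], ] - V[tri[, 1], ]
  e2 <- V[tri[, 3], ] - V[tri[, 1], ]
  areas <- sqrt(rowSums(cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2)) / 2
  expect_true(all(areas > 1e-9))
  expect_true(all(abs(sqrt(rowSums(facetNormals(m)^2)) - 1) < 1e-5))
})

test_that("binary STL layout is exactly 84 + 50 T bytes and parses back", {
  oneTri <- new("TriangleMesh",
                vertices = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3,
                                  byrow = TRUE),
                triangles = matrix(c(1L, 2L, 3L), 1),
                normals = matrix(c(0, 0, 1), 1))
  p1 <- tempfile(fileext = ".stl")
  writeSTL(oneTri, p1)
  expect_identical(file.size(p1), 134)           # 84 + 50 * 1

  vol <- sphereVolume(radius = 4, spacing = 0.5)
  m <- extractIsosurface(vol, 200)
  p <- tempfile(fileext = ".stl")
  writeSTL(m, p)
  nt <- nrow(triangles(m))
  expect_identical(file.size(p), 84 + 50 * nt)

  parsed <- parseBinarySTL(p)
  expect_identical(parsed$count, nt)
  # vertices recovered at 32-bit float precision
  V <- vertices(m); tri <- triangles(m)
  for (i in c(1L, nt %/% 2L, nt)) {
    got <- parsed$facets[[i]]
    expect_equal(got[, 2:4], t(V[tri[i, ], ]), tolerance = 1e-6)
    expect_equal(got[, 1], facetNormals(m)[i, ], tolerance = 1e-6)
  }

  # empty mesh: valid file with count 0
  pe <- tempfile(fileext = ".stl")
  writeSTL(new("TriangleMesh", vertices = matrix(numeric(), 0, 3),
               triangles = matrix(integer(), 0, 3),
               normals = matrix(numeric(), 0, 3)), pe)
  expect_identical(file.size(pe), 84)
  expect_identical(parseBinarySTL(pe)$count, 0L)
})

test_that("ASCII STL follows the solid/facet grammar", {
  vol <- sphereVolume(radius = 3, spacing = 0.5)
  m <- extractIsosurface(vol, 200)
  p <- tempfile(fileext = ".stl")
  writeSTL(m, p, mode = "ascii")
  lines <- readLines(p)
  expect_match(lines[1], "^solid ")
  expect_match(lines[length(lines)], "^endsolid ")
  expect_identical(sum(grepl("^  facet normal ", lines)),
                   nrow(triangles(m)))
  expect_identical(sum(grepl("^      vertex ", lines)),
                   3L * nrow(triangles(m)))
})

test_that("series-to-STL meshes every disjoint bone insert as its own component", {
  d <- newStudyDir()
  spec <- smallPhantomSpec(nSlices = 8L, seed = 61L)
  # two inserts, both strictly interior in z: sphere + capped cylinder
  makePhantomStudy(spec, d)
  sortStudy(d)
  denoiseSeries(file.path(d, "1"))
  p <- tempfile(fileext = ".stl")
  m <- seriesToSTL(file.path(d, "1"), thresholdSpec(), p)
  expect_true(file.exists(p))
  expect_identical(file.size(p), 84 + 50 * nrow(triangles(m)))
  expect_identical(meshComponentCount(m), 2L)

  # all-soft-tissue phantom at a bone iso: empty STL
  d2 <- newStudyDir()
  makePhantomStudy(smallPhantomSpec(nSlices = 2L, seed = 62L,
                                    boneInserts = list()), d2)
  sortStudy(d2)
  denoiseSeries(file.path(d2, "1"))
  p2 <- tempfile(fileext = ".stl")
  m2 <- seriesToSTL(file.path(d2, "1"), thresholdSpec(), p2)
  expect_identical(nrow(triangles(m2)), 0L)
  expect_identical(file.size(p2), 84)
})
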