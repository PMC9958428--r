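# Shared fixtures: compact phantom geometries that keep the suite fast
# while preserving the structural relations of the default clinical-regime
# phantom (body ellipse, disjoint couch arc inside the tissue band, bone
# inserts inside the body).

# 128 px @ 0.5 mm: used wherever masking geometry matters. The body-couch
# gap is 11 px against a closing radius of 3 px, as in the full-size
# default.
smallPhantomSpec <- function(nSlices = 4L, nSeries = 1L, noiseSD = 0,
                             seed = 1L, decoyNonDicom = 0L,
                             decoyCorrupted = 0L, matrixSize = 128L,
                             pixelSpacing = 0.5, boneInserts = NULL, ...) {
  zMid <- nSlices * 0.5 / 2
  if (is.null(boneInserts))
    boneInserts <- list(
      list(type = "sphere", center = c(8, 0, zMid), radius = 4),
      list(type = "cylinder", center = c(-8, 0, zMid), radius = 3,
           halfLength = zMid))
  phantomSpec(
    matrixSize = matrixSize, nSlices = nSlices, nSeries = nSeries,
    pixelSpacing = pixelSpacing, sliceThickness = 0.5,
    bodySemiAxes = c(20, 15),
    tableRadius = 27, tableWidth = 3, tableHalfAngle = 50,
    boneInserts = boneInserts,
    noiseSD = noiseSD, seed = seed,
    decoyNonDicom = decoyNonDicom, decoyCorrupted = decoyCorrupted, ...)
}

newStudyDir <- function() {
  d <- tempfile("study")
  dir.create(d)
  d
}

# Minimal independent binary-STL parser (deliberately not using the
# package's writer internals): header, count, 50-byte facet records.
parseBinarySTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", size = 4L, endian = "little")
  tris <- vector("list", nt)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tris[[i]] <- matrix(vals, nrow = 3L)  # columns: normal, v1, v2, v3
  }
  list(header = header, count = nt, facets = tris)
}

# Undirected edge use counts of a mesh (watertight <=> all exactly 2).
meshEdgeUse <- function(mesh) {
  tri <- triangles(mesh)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# Number of connected components of the triangle graph (union-find).
meshComponentCount <- function(mesh) {
  tri <- triangles(mesh)
  if (nrow(tri) == 0L) return(0L)
  n <- nrow(vertices(mesh))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(tri))) {
    a <- find(tri[i, 1L]); b <- find(tri[i, 2L]); c <- find(tri[i, 3L])
    parent[a] <- b
    parent[find(b)] <- find(c)
  }
  length(unique(vapply(unique(as.vector(tri)), find, 1L)))
}

eulerCharacteristic <- function(mesh) {
  tri <- triangles(mesh)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  nE <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(vertices(mesh)) - nE + nrow(tri)
}

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

digest_bytes <- function(path) unname(tools::md5sum(path))

# Non-pixel element fingerprint of a DICOM file (tag, VR, value bytes) for
# metadata-preservation diffs.
elementFingerprint <- function(path) {
  s <- readSlice(path)
  lapply(c(s@metaElements, s@elements), function(el)
    list(el$group, el$element, el$vr, el$bytes))
}
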