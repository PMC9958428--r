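# Isosurface extraction (marching cubes) and STL export.

#' Extract an isosurface mesh from a CT volume
#'
#' Marching cubes over the voxel grid: the mesh approximates the level set
#' of the trilinear interpolation of the grid at `iso`. Vertices are welded
#' (shared across triangles through global edge identity), mapped to world
#' millimetres through the volume affine, and wound consistently outward
#' (away from the above-iso region). Zero-area triangles (below 1e-9 mm²)
#' are dropped. A field with no iso crossing yields an empty mesh. Where
#' the iso-set exits the grid the surface is left open (no capping).
#'
#' @param volume a [CTVolume-class] with at least 2 voxels per axis.
#' @param iso isosurface level, HU.
#' @param decimate optional fraction in (0, 1): vertex-clustering
#'   decimation retaining roughly this fraction of the resolution (1 =
#'   none, the default; applied before welding-sensitive checks, intended
#'   for lightweight previews only).
#' @return a [TriangleMesh-class].
#' @export
extractIsosurface <- function(volume, iso, decimate = 1) {
  stopifnot(is(volume, "CTVolume"))
  d <- dim(volume@voxels)
  if (any(d < 2L)) stop("extractIsosurface: need >= 2 voxels per axis")
  rng <- range(volume@voxels)
  if (iso <= rng[1L] || iso >= rng[2L])
    return(.emptyMesh())
  vox <- volume@voxels
  if (decimate < 1) {
    stopifnot(decimate > 0)
    step <- max(1L, as.integer(round(1 / decimate)))
    if (step > 1L) {
      idx <- lapply(d, function(n) unique(pmin(seq(1L, n + step - 1L,
                                                   by = step), n)))
      vox <- vox[idx[[1L]], idx[[2L]], idx[[3L]]]
      # spacing grows by the sampling step; rebuild a matching volume
      aff <- volume@affine
      aff[1:3, 1:3] <- aff[1:3, 1:3] * step
      volume <- new("CTVolume", voxels = vox, affine = aff,
                    spacing = volume@spacing * step)
      return(extractIsosurface(volume, iso, decimate = 1))
    }
  }
  core <- .mcCore(as.numeric(vox), dim(vox), iso)
  V <- core$vertices
  Tm <- core$triangles
  if (nrow(Tm) == 0L) return(.emptyMesh())
  # when the iso level hits a lattice value exactly, several edges produce
  # bit-identical vertices at that lattice point; weld them and drop the
  # collapsed triangles, otherwise the surface is not edge-paired
  key <- paste(V[, 1L], V[, 2L], V[, 3L], sep = ",")
  first <- match(key, key)
  if (any(first != seq_along(first))) {
    Tm[] <- first[Tm]
    deg <- Tm[, 1L] == Tm[, 2L] | Tm[, 2L] == Tm[, 3L] |
      Tm[, 1L] == Tm[, 3L]
    Tm <- Tm[!deg, , drop = FALSE]
    used <- sort(unique(as.vector(Tm)))
    V <- V[used, , drop = FALSE]
    Tm[] <- match(Tm, used)
    if (nrow(Tm) == 0L) return(.emptyMesh())
  }
  world <- cbind(V, 1) %*% t(volume@affine)
  V <- world[, 1:3, drop = FALSE]
  e1 <- V[Tm[, 2L], , drop = FALSE] - V[Tm[, 1L], , drop = FALSE]
  e2 <- V[Tm[, 3L], , drop = FALSE] - V[Tm[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 / 2 > 1e-9
  Tm <- Tm[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]
  normals <- cr / sqrt(rowSums(cr^2))
  # the affine may flip handedness (LPS->RAS negates two axes); keep the
  # winding outward in world space
  if (det(volume@affine[1:3, 1:3]) < 0) {
    Tm <- Tm[, c(1L, 3L, 2L), drop = FALSE]
    normals <- -normals
  }
  new("TriangleMesh", vertices = V, triangles = Tm, normals = normals)
}

.emptyMesh <- function()
  new("TriangleMesh",
      vertices = matrix(numeric(), 0L, 3L),
      triangles = matrix(integer(), 0L, 3L),
      normals = matrix(numeric(), 0L, 3L))

#' Total surface area of a mesh
#' @param mesh a [TriangleMesh-class].
#' @return area in mm^2.
#' @export
meshArea <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (nrow(mesh@triangles) == 0L) return(0)
  V <- mesh@vertices; Tm <- mesh@triangles
  e1 <- V[Tm[, 2L], , drop = FALSE] - V[Tm[, 1L], , drop = FALSE]
  e2 <- V[Tm[, 3L], , drop = FALSE] - V[Tm[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; meaningful for
#' watertight meshes with consistent outward winding (then positive).
#'
#' @param mesh a [TriangleMesh-class].
#' @return signed volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (nrow(mesh@triangles) == 0L) return(0)
  V <- mesh@vertices; Tm <- mesh@triangles
  a <- V[Tm[, 1L], , drop = FALSE]
  b <- V[Tm[, 2L], , drop = FALSE]
  cc <- V[Tm[, 3L], , drop = FALSE]
  cr <- cbind(b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L],
              b[, 3L] * cc[, 1L] - b[, 1L] * cc[, 3L],
              b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  sum(rowSums(a * cr)) / 6
}

.STL_HEADER_SIG <- "ctprep binary STL"

#' Write a mesh as an STL file
#'
#' Binary layout (default): 80-byte header carrying a fixed tool signature
#' padded with nulls, a 4-byte little-endian unsigned triangle count, then
#' 50 bytes per triangle — 12 little-endian 32-bit floats (normal, three
#' vertices) and a 2-byte attribute count of zero. File size is therefore
#' exactly `84 + 50 * nTriangles` bytes. ASCII mode writes the
#' `solid`/`facet normal`/`endsolid` grammar. An empty mesh produces a
#' valid file with triangle count 0.
#'
#' @param mesh a [TriangleMesh-class].
#' @param outPath output path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return invisibly, the path written.
#' @export
writeSTL <- function(mesh, outPath, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(is(mesh, "TriangleMesh"))
  nt <- nrow(mesh@triangles)
  dir.create(dirname(outPath), recursive = TRUE, showWarnings = FALSE)
  if (mode == "binary") {
    con <- file(outPath, "wb")
    on.exit(close(con))
    header <- charToRaw(.STL_HEADER_SIG)
    writeBin(c(header, raw(80L - length(header))), con)
    writeBin(as.integer(nt), con, size = 4L, endian = "little")
    if (nt > 0L) {
      # per-facet record: normal, v1, v2, v3 (floats), attribute 0
      V <- mesh@vertices; Tm <- mesh@triangles
      rec <- rbind(t(mesh@normals), t(V[Tm[, 1L], , drop = FALSE]),
                   t(V[Tm[, 2L], , drop = FALSE]),
                   t(V[Tm[, 3L], , drop = FALSE]))   # 12 x nt
      flRaw <- matrix(writeBin(as.vector(rec), raw(), size = 4L,
                               endian = "little"), nrow = 48L)
      writeBin(as.vector(rbind(flRaw, matrix(raw(2L * nt), nrow = 2L))),
               con)
    }
  } else {
    con <- file(outPath, "w")
    on.exit(close(con))
    writeLines("solid ctprep", con)
    V <- mesh@vertices; Tm <- mesh@triangles
    for (i in seq_len(nt)) {
      n <- mesh@normals[i, ]
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        v <- V[Tm[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]),
                   con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid ctprep", con)
  }
  invisible(outPath)
}

#' Series to STL bone-surface mesh
#'
#' The full mesh chain on a sorted, denoised series: [stackSeries()],
#' [extractIsosurface()] at the bone band's lower edge, [writeSTL()].
#'
#' @param seriesDir sorted series directory.
#' @param spec a [ThresholdSpec-class]; `boneLower` is the iso level.
#' @param outPath STL output path.
#' @param mode `"binary"` or `"ascii"`.
#' @param decimate see [extractIsosurface()].
#' @return invisibly, the [TriangleMesh-class] written.
#' @export
seriesToSTL <- function(seriesDir, spec = thresholdSpec(), outPath,
                        mode = c("binary", "ascii"), decimate = 1) {
  mode <- match.arg(mode)
  vol <- stackSeries(seriesDir)
  mesh <- extractIsosurface(vol, iso = spec@boneLower, decimate = decimate)
  writeSTL(mesh, outPath, mode)
  invisible(mesh)
}
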