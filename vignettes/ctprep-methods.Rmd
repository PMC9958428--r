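---
title: "ctprep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctprep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctprep)
```

This vignette records the models, parameter choices and numerical
decisions behind `ctprep`, in the spirit of a methods section: what the
pipeline computes, under which assumptions, and where the genuinely open
design choices were resolved.

## The problem and the model

A CT study is a directory of DICOM slices, each a 2-D matrix of stored
integers plus tagged metadata. Stored values are related to radiodensity
in Hounsfield units (HU) by a per-file linear rescale,

$$ \mathrm{HU} = \mathrm{stored} \cdot \mathrm{slope} + \mathrm{intercept}, $$

with air near −1000 HU, water at 0, soft tissue roughly 20–80, trabecular
to cortical bone 200–3000. Every clinical scan also images the patient
support ("sliding table" or couch) and often tubing or clothing. These
structures overlap soft tissue and even bone in radiodensity, so a pure
threshold cannot remove them. What does separate them from the patient is
*connectivity*: the couch never touches the body. The denoising model is
therefore:

1. threshold the HU image to a wide *tissue band* (default −300 to
   3000 HU) that captures everything from fat to cortical bone;
2. morphologically close the binary image (disc, radius 3 px) so that thin
   anatomical gaps do not fragment the patient;
3. keep the single largest connected component — the patient cross-section
   dominates the couch cross-section in any clinical field of view;
4. fill interior holes (lungs, bowel gas belong to the patient);
5. set stored values outside this mask to 0 and overwrite the file in
   place, leaving every other metadata element byte-identical.

Everything *inside* the patient envelope is deliberately kept: removal of
in-body foreign objects (stents, internal tubing) is out of scope, and a
mask that kept only bone would destroy the soft-tissue context that some
downstream applications need.

### Why stored 0, not an HU value

"Background" must be expressed in stored units because that is what the
file holds. With the typical CT intercept of −1024, stored 0 reads back as
−1024 HU — air — which is the physically sensible background. The HU
meaning of the background therefore depends on the file's intercept; this
is documented rather than "fixed", because writing intercept-dependent
stored values would break byte-level idempotence.

### Per-slice versus volumetric masking

Whether the original procedure masked each slice independently or on the
stacked volume is unknowable from the outside; both are provided
(`mode = "slice"` / `"volume"` in `denoiseSeries()`). Volumetric mode
stacks the thresholded slices and keeps the largest 6-connected 3-D
component, which is the robust choice where a per-slice "largest
component" is ambiguous (slices through the legs see two similar
components). For any geometry where the couch is disconnected from the
body in 3-D, the two modes give identical masks; the tests assert exactly
that on phantoms.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| tissue band | −300 … 3000 | HU | fat through cortical bone; couch materials fall inside it on purpose — removal must come from connectivity, not thresholding |
| bone band | 200 … 3000 | HU | trabecular onset to the 12-bit ceiling; also the mesh iso level |
| closing radius | 3 | px | bridges anatomical gaps ~3 mm at 0.5 mm pitch without bridging the ≥ 5 mm body–couch gap |
| window | 200 … 3000 → 0 … 255 | HU | bone-centred display window; `binary = TRUE` gives hard 0/255 thresholding since "thresholded 2-D export" can mean either |
| JPEG quality | 95 | — | near-lossless at typical CT texture |
| slice-spacing tolerance | 1e-3 | mm | gaps are a hard error, never silently resampled — resampling would corrupt morphometry |
| STL mode | binary | — | 84 + 50·T bytes; ASCII for interchange/debugging |

All bands are configurable (YAML config or CLI flags), so any tissue of
interest can be highlighted, not just bone.

## The phantom generator

`makePhantomStudy()` emulates the aspects of a clinical study the pipeline
actually consumes: 12-bit unsigned stored pixels with slope 1 / intercept
−1024, per-slice geometry tags (position, orientation, spacing,
thickness), several series interleaved in one directory, decoy non-DICOM
and truncated files, an elliptical soft-tissue body (40 HU), spherical and
cylindrical bone inserts (700 HU), and a couch arc (150 HU) strictly
outside the body. Defaults mirror a modern clinical acquisition regime:
512 × 512 matrix, 0.5 mm pixel spacing and slice thickness.

Two generator choices deserve justification:

* **The couch sits inside the tissue band.** At 150 HU it survives
  thresholding, so every passing table-removal test demonstrates that the
  connected-component logic works — not that a threshold happened to
  exclude the couch.
* **Edges are partial-volume ramps, not steps.** Real CT edges are blurred
  by the scanner PSF and in-voxel averaging; material boundaries are
  rendered with a linear ramp of fixed physical width (default 0.5 mm, the
  one-voxel partial-volume minimum at the default grid). A hard binary
  step would be both unrealistic and metrologically misleading: marching
  cubes over a binary field measures the staircase bias of the field
  (≈ +6–8 % sphere area) rather than the extractor's accuracy.

What the phantom does **not** emulate: anatomical texture, beam-hardening
and streak artifacts, contrast phases, metal implants, non-axial
orientations in the generator (the reader and stacker handle arbitrary
orthonormal orientations, the generator always writes axial slices).
Passing tests therefore show correctness of the pipeline mechanics on
clean geometry, not robustness to every clinical artifact.

Determinism: a phantom's seed fully determines its bytes; noise is
additive Gaussian in HU before quantisation, and at `noiseSD = 0` stored
values are exactly the quantised material HUs.

## Geometry: DICOM to NIfTI

Slices are ordered by the projection of `ImagePositionPatient` onto the
slice normal (the cross product of the row/column direction cosines) —
robust to reversed acquisitions; a mismatch with instance-number order is
reported. The voxel-index→world affine is assembled from the direction
cosines, pixel spacing and the inter-slice step, in the DICOM patient
(LPS) frame, then converted to NIfTI's RAS convention by negating the
first two world axes *in the affine only* — voxel data are never flipped,
so the conversion is lossless. HU values are written as signed 16-bit with
scale slope 1 (they already are HU). Inter-slice spacing must be uniform
to 1e-3 mm.

## Isosurface extraction

The mesh approximates the iso-level set of the trilinear interpolant of
the voxel grid, extracted cube-by-cube with the classic 256-case
marching-cubes triangulation table and linear interpolation along cell
edges. Implementation choices:

* **Welded vertices.** Each surface vertex lies on a unique lattice edge;
  a global edge key shares it across all incident triangles. Watertightness
  can then be checked structurally (every undirected edge used by exactly
  two triangles) instead of geometrically.
* **Classic table rather than a sub-case (Lewiner-style) table.** The full
  topologically-consistent sub-case machinery resolves face ambiguities
  that arise only in saddle configurations at the voxel scale. On the
  smooth, resolved fields this package targets (and generates), those
  configurations do not occur; the suite verifies closedness (edge pairing
  and Euler characteristic 2) on every phantom mesh. The classic table was
  validated during development against an independent marching-cubes
  implementation on shared fields (identical triangle counts and areas).
* **Iso level on lattice points.** When the level exactly equals a grid
  value, several cell edges emit the same lattice-point vertex; these are
  welded by exact position and collapsed triangles removed, restoring edge
  pairing. Remaining triangles below 1e-9 mm² are dropped.
* **Winding and orientation.** Triangles are wound so normals point away
  from the above-iso (interior) region; if the affine is left-handed (the
  LPS→RAS conversion of an axial series is), the winding is flipped once
  in world space. The divergence-theorem volume of a closed mesh is then
  positive.
* **Open boundaries.** Where the iso-set exits the grid the surface is
  left open — no capping is invented.
* **No smoothing or decimation by default.** The surface is exactly what
  the data support; an optional vertex-clustering decimation
  (`decimate` < 1, implemented as grid subsampling) exists for previews.

The standard accuracy fixture is `sphereVolume()`: a clamped linear radial
ramp calibrated so that the chosen iso level lies exactly on the stated
sphere radius. Against the analytic sphere the extractor achieves ~0.1 %
surface-area error at 0.5 mm spacing and ~0.02 % at 0.25 mm; enclosed
volume is within 0.4 % at 0.25 mm. Halving the spacing must reduce the
area error — asserted in the tests.

## DICOM I/O scope and numerical details

The reader/writer supports Part-10 files (128-byte preamble + `DICM`),
explicit and implicit little-endian transfer syntaxes, uncompressed pixel
data, 8/16-bit, signed or unsigned. Compressed syntaxes, enhanced
multi-frame CT and DICOMDIR are out of scope. Classification is total:
`non_dicom` when the format signature is absent, `corrupted` when the
signature is present but parsing, required-attribute decoding
(pixel data, dimensions, rescale, spacing, position, orientation, series
identity) or pixel decoding fails. Elements the pipeline does not
interpret are carried as raw bytes in original order, which is what makes
the overwrite metadata-preserving at the byte level. Stored values are
clamped on write to the range declared by the file's bit depth and pixel
representation, preventing silent integer overflow.

The tag pair (0020,000E) is the Series *Instance UID*; the Series *Number*
is (0020,0011). Series identity uses the UID (globally unique), while the
sorted subfolder is *named* by the number, matching the layout users
expect; two UIDs sharing a number get deterministic `-2`, `-3` suffixes.
Within a series, files order by instance number with filename as
tie-break. Round-half-up is used at the image-window midpoint (R's
`round()` halves to even, which would map the midpoint down).

## Problem sizes in the suite

Unit and acceptance tests run on compact phantoms (64–128 px in plane,
2–16 slices) that preserve the structural ratios of the full-size default
— in particular an 11 px body–couch gap against the 3 px closing radius,
the same proportion regime as the 512 px default. The matrix-preservation
check runs on a full 512 × 512 slice; couch-removal fidelity is evaluated
on twenty phantoms at noise levels 0–20 HU; the mesh oracle runs at 0.5
and 0.25 mm spacing. The whole suite and the acceptance script each finish
in well under a minute on a single core.

## Known limitations

* Per-slice masking assumes the patient is the largest in-plane component;
  use volumetric mode for extremity or leg series.
* A couch touching the patient (blankets bridging the gap) would join the
  patient component; the closing radius must stay below half the
  body–couch gap.
* The DICOM subset excludes compressed transfer syntaxes; such files are
  classified `corrupted` (signature present, unsupported encoding) rather
  than silently skipped.
* STL output is a raw marching-cubes surface: fine for measurement and
  printing pipelines that do their own repair/decimation, but no mesh
  cleanup is performed here.
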