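---
title: "Two-branch 3D reconstruction of serial histological sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-branch 3D reconstruction of serial histological sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histo3d)
```

## The problem

Serial sectioning cuts a paraffin-embedded tissue block into consecutive
thin slices (here 5 μm), each of which is immunostained (DAB brown over a
pale hematoxylin counterstain) and photographed as a 24-bit RGB image.
Stacking the 2D photographs approximates the 3D tissue volume, which makes
it possible to ask genuinely three-dimensional questions — most importantly
whether duct-like stained structures form one *connected* network with the
bile ducts of the portal area, or sit as *isolated* aggregations in the
parenchyma. A 2D section cannot distinguish the two; the 3D reconstruction
can.

`histo3d` implements the complete digital half of that workflow as two
complementary branches operating on the same aligned stack:

1. **Volumetric rendering.** The edited, color-inverted sections are
   recombined into an RGBA voxel grid; an alpha (opacity) channel is derived
   from the inverted colors; the colors are re-inverted (`v * -1 + 255` per
   channel, alpha passing through); and the volume is projected to 2D by
   front-to-back alpha compositing or maximum-intensity projection. This
   branch is fast and unbiased — no structure has to be outlined by hand —
   but produces pictures, not objects.
2. **Segmentation-based surface rendering.** Grayscale versions of the
   enhanced stacks are labeled by thresholding (plus optional manual masks),
   cleaned by component-size filtering, analyzed by 3D connected components
   and connectivity queries against a reference structure (the vessel
   lumina), and turned into explicit triangle meshes — deliberately
   *without any smoothing*, so the mesh is an honest piecewise-linear view
   of the labeled voxels.

The interactive imaging steps of the original bench workflow (slice
alignment, contrast adjustment, background cleanup, color-range noise
removal) are replaced by deterministic, parameterized operators so that
every run is reproducible from its configuration; the pipeline records all
parameters in its report.

## Stack geometry and bookkeeping

Sections are indexed by their 0-based *cut position*; section `i` sits at
depth `i × thickness_um`. The z-extent of a stack is
`(max_index − min_index + 1) × thickness_um`: a section excluded from
imaging still occupies depth in the block, so gaps never shorten the
reconstruction. Under the reference conditions — fifty 5-μm sections — the
stack spans 250 μm, and with markers interleaved every 10th section each
marker appears 5 times:

```{r bookkeeping}
m <- stack_manifest(data.frame(index = 0:49, file = NA), thickness_um = 5)
z_extent(m)
length(marker_schedule(50, interval = 10))
```

When sections are dropped (damaged or unusable), two voxelization policies
are possible: leave the slot empty (gap-skip) or copy the nearest included
section. The package defaults to gap-skip because duplication invents data;
nothing in the protocol prescribes duplication.

## Rigid alignment

Consecutive sections are aligned by a rigid transform (rotation +
translation, no scaling — scaling would corrupt the physical pixel size).
The landmark path solves the 2D orthogonal Procrustes problem in closed
form; rotation is taken about the image center so that the angle and the
translation are decoupled, matching how manual slice alignment behaves.
Pairwise transforms are chained to the first included section, which serves
as the reference frame (the workflow it replaces is interactive and silent
on this; chaining with a declared reference is the reproducible choice).
Resampling is inverse-mapping with bilinear interpolation for display
images and nearest-neighbor for label masks (bilinear would mix label
ids), and out-of-canvas samples are filled with pure white — consistent
with the downstream convention that background is forced to pure white.

`auto_align_pair()` offers a convenience alternative (phase correlation for
translation, optional coarse angular search); it is documented as a
heuristic and the landmark path remains the reference behavior.

## The editing operators

All operators are deterministic, clip to `[0, 255]`, and never touch pixels
outside their selection:

* `adjust_brightness_contrast()`: `v' = clip(slope·(v − 128) + 128 + offset)`.
* `whiten_background()`: pixels within a per-channel tolerance (default 12
  gray levels) of the background color — estimated as the modal color of
  the 1-px image border unless supplied — are set to pure white.
* `remove_color_range_noise()`: pixels near a target color (the dark
  debris color) are selected; the selection is refined by morphological
  closing-then-opening (radius 1 px by default, through EBImage); selected
  2D regions smaller than `min_noise_size` (default 30 px) are whitened,
  larger ones — genuine stain — are kept bit-exactly.
* `invert_channels()`: `v → 255 − v`, an involution; the same formula is the
  re-inversion applied after channel recombination.
* `resize_section()`: the protocol halving (e.g. a 1392×1040 camera frame
  to 696×520) is 2×2 block averaging — the antialiasing-correct choice for
  downsizing — with the recorded pixel size doubled. The "50 pixels per
  inch" of the original protocol is display metadata and plays no role in
  geometry.
* `to_grayscale()`: Rec. 601 luma (0.299, 0.587, 0.114); the original
  workflow names no formula, so the broadcast-standard weights are used.
* `enhance_lumina()`: the vessel-lumen series needs tissue darkened and
  lumina pushed to white. This is implemented as an idempotent tone clamp:
  near-white pixels (every channel within `lumen_tolerance`, default 35, of
  255) go to pure white; all other pixels are capped per channel at
  `lumen_ceiling` (default 170). Both halves are projections, so applying
  the operator twice changes nothing and a pure-white pixel is never
  darkened. A slope-based darkening was considered and rejected because it
  is not idempotent: re-running a pipeline stage would keep darkening the
  same image. The tolerance of 35 is chosen to capture a rendered lumen
  (blue channel ≈ 236) under ±4 SD of the default channel noise while
  staying far above the counterstain (whose red channel ≈ 190 keeps it
  outside any near-white test).

Since the interactive tools these operators replace publish no numeric
settings, the defaults above were fixed once on phantom fixtures and are
recorded in every run report. Whether weak stains should additionally be
darkened is exposed as a per-branch parameter rather than guessed by a
heuristic.

## Volumetric rendering

`build_rgba_volume()` stacks the inverted sections into an `H×W×Z×4` grid.
The opacity rule is `A = max(R_inv, G_inv, B_inv)`: a pixel that was pure
white (slide background) inverts to black and becomes exactly transparent,
while any stain acquires opacity proportional to its strongest inverted
channel. The tool this emulates computes its alpha "automatically" without
publishing a formula, so the max rule is a documented convention — chosen
because it guarantees transparent background and visible stain — and
`alpha_rule = "luminance"` or `"mean"` are available alternatives. It
cannot be validated against the original figures and is not claimed to
match them.

The default voxel spacing is `(1, 1, 10)` — the protocol's own (explicitly
arbitrary) convention that stretches the thin stack into visible depth; the
physical alternative `(pixel_size, pixel_size, thickness × interval)` is a
flag away. Compositing works front-to-back in normalized opacity,
`C += (1 − A_acc)·a_i·C_i`, with early exit at accumulated opacity 0.999
and the residual weight filled with the background color; `"mip"` takes the
per-ray channel-wise maximum of alpha-weighted color, showing the
background only along rays that met no opacity at all. Integer `[0, 255]`
storage is kept end to end; compositing is done in floating point and
re-quantized once. Off-axis orthographic views resample the volume with
nearest-voxel lookups at ray steps of `min(spacing)/2`; axis-aligned views
composite the voxel slices directly and stretch the off-plane axis by the
anisotropy ratio.

## Segmentation and connectivity

Thresholding assigns each voxel to the first matching label spec in list
order (first-match-wins mirrors an exclusive per-voxel segmentation
editor); `"dark"` polarity selects `v ≤ t` (stains), `"bright"` selects
`v ≥ t` (whitened lumina). Manual masks can add or erase label regions per
section. The slide background is bright in exactly the way lumina are, so
the lumen label is cleaned by dropping components that touch the in-plane
image border — interior lumina cannot.

Connected components use 26-adjacency by default. This matters: with 10×
z-anisotropy (and worse, every-10th-section marker sampling) a duct
crossing sections obliquely advances more than one voxel in-plane per
z-step, and face-only 6-adjacency would artifactually disconnect it;
6 and 18 remain selectable. For interleaved markers, connectivity for one
marker is computed on that marker's own subsampled stack with z-adjacency
between consecutive sampled sections. Components are relabeled in
decreasing size order so runs are bit-for-bit deterministic.

The biological question "is this stained structure connected to the duct
system?" is formalized by `connectivity_query()`: a stain component is
**connected** iff it contains, or is adjacent to under the same
connectivity rule, at least one voxel of the reference region (a label —
typically the vessel lumina — or an explicit seed voxel set); otherwise it
is **isolated**. The original study states this finding qualitatively; the
adjacency definition here is this package's formalization of it.

## Surface generation without smoothing

Meshes are extracted at iso-level 0.5 of the binary label mask using a
tetrahedral marching-cubes decomposition: each grid cell is split into the
six Kuhn tetrahedra (whose face diagonals agree between neighboring cells)
and the linear isosurface is emitted per tetrahedron. On binary data every
isosurface vertex is an edge midpoint, there are no ambiguous
configurations to resolve, and the surface is watertight by construction —
every edge borders exactly two triangles. This decomposition was chosen
over the classic 256-case cube lookup table precisely because the cube
table needs an ambiguity decider to avoid holes, and on binary data the
decider's quantities tie; the tetrahedral variant has no such failure mode.
No vertex smoothing or decimation exists anywhere in the pipeline — flat
mask faces stay planar to machine precision, and the voxel-step "staircase"
in z is a faithful statement of the 10× anisotropy rather than an artifact
to hide.

Vertex coordinates are voxel indices scaled by the volume spacing (physical
micrometres when available), so meshes of different labels overlay in one
space. `mesh_measures()` reports triangle count, area, enclosed volume
(signed tetrahedron sum, reported only when the mesh is closed), shell
count and Euler characteristic; `export_mesh()` writes PLY (ASCII or binary
little-endian, with the label color as per-vertex color), OBJ (1-based
indices) and STL. A marching-cubes-style mesh of a discrete solid
slightly undercuts corners: a 10³-voxel cube meshes to ≈ 993 voxel-units³
(−0.7%) and a radius-8 digitized sphere to within a few percent of
`4/3·π·r³` — the acceptance tolerances (5% and 10%) come from those fixture
measurements.

## The phantom: what it emulates and what it does not

Human tissue and the original photographs are not distributable, so the
test substrate is a synthetic branching-duct phantom with exact ground
truth. `generate_tube_tree()` grows a recursive tube tree — lumen plus
stained wall, optionally sheathed by an annular "ductal-plate" sleeve — on
an isotropic micrometre grid, plus deliberately detached stained spheres
(the ground-truth analogue of stained aggregations without duct
connection). `virtual_sections()` then cuts the grid into 5-μm sections and
renders them with DAB-plausible colors, per-channel Gaussian noise and
Poisson-placed dark specks; `perturb_alignment()` injects per-section rigid
misalignment and returns the exact inverse transforms. All randomness flows
from a single seed; identical specs are bit-identical.

Default study conditions: a 240 × 240 × 250 μm block on a 2.5-μm grid —
fifty 5-μm sections of 96 × 96 px, the protocol's section count and
thickness at a resolution that keeps the full suite fast — trunk radius
22 μm with a 7.5-μm stained wall, two binary branching levels (segment
lengths shrinking by 0.7 and radii by 0.8 per level, branch angles
15–35°), stain (120, 70, 40), counterstain (190, 175, 210), background
(248, 247, 245), channel noise SD 4, 50 specks/mm². These are plausibility
choices for DAB/hematoxylin appearance, fixed once and recorded here; they
are not measurements from any specimen.

What the phantom deliberately does **not** emulate: real histological
texture (nuclei, cytoplasmic granularity, stain gradients within a
structure), section stretching and folding, uneven illumination, staining
batch effects, or the embryologically structured geometry of real ductal
plates. Passing phantom tests therefore demonstrates that the *operators
and their composition* are correct — alignment recovers known transforms,
segmentation recovers known masks, connectivity matches known topology —
not that the default thresholds are optimal for any particular real stain.
On real material the thresholds and editing parameters are expected to need
per-marker tuning, which is why every one of them is a config value
captured in the run report.

## Numerical choices and degenerate inputs

* Compositing early-exit at accumulated opacity 0.999; off-axis ray step
  `min(spacing)/2`.
* Iso-level 0.5 on binary masks; mesh vertices deduplicated by exact
  integer (doubled-coordinate) keys, so watertightness is not at the mercy
  of floating-point comparisons.
* Overlapping label specs resolved by list order (first match wins);
  component ids assigned in decreasing size order for determinism.
* Gap filling under the `"nearest"` policy breaks distance ties toward the
  earlier section.
* Empty label → empty mesh with a warning, not an error; an open mesh
  reports its volume as `NA` rather than a number.
* Landmark fits require ≥ 2 non-coincident pairs; constant images are
  rejected by the phase-correlation aligner; phantom trees that would leave
  the grid are rejected with a message suggesting a larger extent.
* JPEG is accepted as input but bit-exact round-trips are promised only for
  uncompressed TIFF and PNG (JPEG quality default 0.95).

## Problem sizes

The shipped tests run the full-protocol phantom (fifty 5-μm sections,
96 × 96 px) for the end-to-end and alignment-recovery properties, a reduced
24-section phantom for per-operator checks, 20 seeded random masks of
10 × 10 × 5 voxels against the flood-fill oracle, and the 10³ cube and r=8
sphere mesh fixtures. The complete suite runs in well under a minute on one
CPU.

## Known limitations

* Rigid alignment only: section stretching, folding and elastic distortion
  are out of scope (the grayscale representation would admit such filters,
  but none are implemented).
* The alpha rule is a convention, not a reverse-engineered match of the
  original tool's formula.
* `connectivity_query()` is adjacency-based; it does not measure anatomical
  continuity of lumens (a wall-to-wall contact counts as connected).
* Orthographic cameras only; no GPU, no interactive viewer.
* Stain-vector color deconvolution (DAB/hematoxylin unmixing) is not
  implemented; all operators work in plain RGB contrast space.
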