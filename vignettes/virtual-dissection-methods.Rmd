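---
title: "Methods: VOI-based virtual dissection and reproducibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOI-based virtual dissection and reproducibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtract)
```

## The model

A whole-brain tractogram is an unordered set of streamlines — polylines in
world millimetre coordinates (RAS+) tied to a reference voxel grid
(shape + 4×4 affine). A *bundle definition* is a declarative rule over
binary volumes of interest (VOIs): a streamline belongs to the bundle iff
it intersects **every** inclusion VOI (logical AND), intersects **no**
exclusion VOI (logical OR over exclusions), and — where termination
semantics are declared — has a terminal point inside each endpoint VOI.
Selected bundles then pass through an arc-length filter, a statistical
outlier filter, and smoothing.

The assumptions are those of any parcellation-driven dissection protocol:
the parcellation and the tractogram share one coordinate space (no
registration is performed here — that is an explicit non-goal), the
parcellation's labels are anatomically meaningful, and streamline geometry
is accurate at the scale of the VOIs.

### Intersection testing

A polyline can cross a one-voxel VOI between two of its vertices. Every
intersection test therefore resamples the polyline by arc length at a
spacing no larger than `step_mm`, endpoints always included, and tests the
samples under the voxel-center convention (a world point belongs to voxel
`i` iff its continuous voxel coordinate lies in `[i − 0.5, i + 0.5)` per
axis; out-of-grid samples are ignored, never clamped). The default
`step_mm` is **half the smallest voxel dimension**, which prevents
tunneling at the 1.25–2.5 mm voxel sizes typical of diffusion MRI. The
density map uses the identical sampling contract, so selection and density
agree about which voxels a streamline visits.

### The failure rule

A dissection *fails* when fewer than `min_streamlines` (default **10**)
streamlines are present initially, or fewer than `min_streamlines` survive
the first filtering step. In whole-brain-then-segment mode there is no
per-bundle seeding count, so "initial" is bound to the post-selection
count; the unnamed "first filtering step" is bound to the arc-length
filter. Both bindings are design decisions of this package and are fixed
so the boundary behaviour (9 → failed, 10 → not failed) is testable.

### The outlier filter

The upstream protocol defers streamline filtering to external data-driven
tools without printing a rule, so this package documents its own: each
streamline is resampled to 32 equidistant points; pairwise symmetric
mean-closest-point (MCP) distances are computed; the *medoid* is the
streamline minimizing the summed distance to all others; streamlines whose
distance to the medoid exceeds `mean + z·sd` of the medoid distances are
removed. MCP is invariant to the direction a streamline was tracked in
(nearest-point search ignores point order), so no flip handling is needed.
Bundles with fewer than 3 streamlines, or with zero spread, pass
unchanged.

### Smoothing

A centered moving average of odd width (default 3) over each coordinate
sequence, window shrunk near the ends, the two endpoints kept fixed. On
realistic curvature this changes arc length by well under 20%; an
adversarial sawtooth can lose more — the contract is about plausible
streamline geometry, not worst cases.

## The 68-bundle registry

The default registry reproduces the protocol structure exactly: 15
bilateral association families (AF, CCing, TCing, FX, FAT, IFOF, ILF,
MdLF, SLF_whole, SLF_I, SLF_IId, SLF_IIv, SLF_III, UF, VOF), 8 commissural
bundles (AC plus the corpus callosum in 7 segments), 12 bilateral
projection families (ML, OT, OR, OR_OL, PyT_all, CST, M1_CST, PyT_PMC,
PyT_SMA, ATR, STR, PaTR) and 3 bilateral cerebellar families (DRTT, ICP,
MCP) — 68 definitions. The posterior thalamic radiation is an alias of
OR_OL, not a 69th entry.

The real protocol binds its VOIs to FreeSurfer/MSBP/atlas label ids that
live outside this package; the default registry instead uses a **symbolic
label vocabulary** (26 bilateral cortical/subcortical region names plus
`brainstem` and `optic_chiasm`) that resolves against the schematic
`atlas_parcellation()`. The include/exclude logic per bundle is anatomically
motivated (e.g. the AF excludes the precentral label; commissural bundles
require both hemispheres' labels plus a midsagittal slab) but the geometry
is a stand-in. Real atlas ids can be transcribed into a registry JSON file
and loaded with `load_registry(path)`; the JSON schema mirrors the
constructors (`bundle_definition()`, `voi_spec()`) one-to-one. JSON was
chosen because it is the one structured-text format with a parser in this
package's minimal dependency set.

Midsagittal slabs use the half-open band `[−t/2, t/2)` around the grid
center's x-coordinate: on even-sized grids a one-voxel slab deterministically
resolves to the lower index. Dilation VOIs use 6-connectivity; box VOIs use
closed boundaries on voxel centers. All three tie-breaks are arbitrary but
fixed, because density-map reproducibility requires byte-stable masks.

## Reproducibility statistics

All similarity measures operate on voxel maps, not on streamline
correspondences (streamline-specific variants are known to underestimate
tractogram similarity). The density map counts *streamline visits*: each
streamline contributes 1 to each distinct voxel it traverses — not a point
count, not length-weighted — which makes the weighted Dice score
scale-free in streamline count.

* **wDSC** normalizes each map to proportions
  `p_X(v) = counts_X(v)/Σcounts_X` and sums `(p_A + p_B)/2` over the shared
  support. Proportions (rather than raw counts) let a 500-streamline and a
  25-streamline bundle be compared fairly; this density-proportion
  weighting follows the cited weighted-Dice construction.
* **DSC**, **overlap/overreach** and **bundle adjacency** are computed on
  binarized maps; adjacency is implemented on voxel masks (symmetric mean
  nearest-voxel distance of the non-shared parts, in mm), a deliberate
  voxel-space variant of the streamline-space original. Two empty masks
  have DSC defined as 1 and flagged, so all-failed comparisons do not
  crash summary pipelines.
* **Density correlation** is Pearson on raw counts over the union of
  supports; undefined (error) under zero variance.
* **ICC** is the two-way random-effects, absolute-agreement,
  single-measure form, with Satterthwaite-approximated F confidence bounds
  at a fixed 95% level and a p-value from `MSR/MSE`. The item axis is the
  caller's choice; the CLI defaults to bundle×subject units.
* **Max.A.I.D.** is expanded as *maximum absolute inter-session
  difference* — an interpretation (the source never defines the
  abbreviation), documented as such.

## The phantom generator

`make_phantom()` emulates the features of real data that the pipeline must
be sensitive to, and nothing more: multiple bundles of very different
streamline counts (dense 500-streamline "pyt_like" vs a 20× sparser
25-streamline "fx_like"), distinct geometries (straight, arcs, a
commissural arch crossing the midline), endpoint regions that double as
parcellation labels, distractor streamlines that avoid all regions, and
test–retest replicates (identical geometry, independent jitter draws).

Each streamline is the centerline translated by a constant random offset
drawn from an isotropic Gaussian (sd = `jitter_mm`, default **1 mm** —
sub-voxel, of the order of tractography scatter) projected onto the plane
perpendicular to the chord; perpendicular distances therefore follow a
Rayleigh(`jitter_mm`) law with mean `jitter_mm·√(π/2)`, which is the
closed form the Monte-Carlo test checks. The default scene uses a 40×44×40
grid at 1 mm with 100 distractors and endpoint boxes of 6–8 mm half-extent
8+ mm apart, chosen once as a realistic miniature of bundle/VOI size
ratios.

What a green phantom test does **not** establish: anything about fODF
quality, tracking algorithms, registration, partial-volume effects, or
real anatomical variability. The phantom validates the selection logic,
the density/metric algebra and the failure machinery — the parts this
package owns.

## Numerical choices and degenerate inputs

* 0-based voxel indices, half-open voxel-center cells; world↔voxel is an
  exact inverse pair on voxel centers.
* TCK carries no reference grid on disk; wmtract writes private `wmt_dim`
  / `wmt_affine` header fields (legal MRtrix free-form keys) so its own
  files round-trip the grid, and accepts an explicit grid for foreign
  files. TRK's corner-origin voxel-mm convention is converted on read and
  write; both formats were cross-validated against nibabel.
* Coordinates round-trip within 1e-4 mm (float32 on disk); integer NIfTI
  volumes round-trip bit-exactly.
* Empty tractograms are valid everywhere (empty density maps, all-failed
  dissections, exit status 0 from the CLI — a completed analysis with
  failures is not a crash).
* Seeds: every stochastic generator takes an explicit seed and restores
  the caller's RNG state; scene-level seeds derive per-bundle seeds by
  fixed offsets, all below 2^31.

## Known limitations

* No tractography, no fODFs, no SIFT/ACT filtering, no registration:
  inputs must already share a space.
* The default registry's VOI geometry is symbolic; census, logic and
  schema are exact, label tables are stand-ins.
* Bundle adjacency is voxel-based; Hausdorff distance is intentionally
  absent.
* The outlier filter's O(n²) distance matrix is fine for dissected bundles
  (10²–10³ streamlines) but is not meant for whole-brain inputs.
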