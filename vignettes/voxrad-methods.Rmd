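---
title: "voxrad: methods, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxrad: methods, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxrad)
```

`voxrad` computes IBSI-style radiomic features from a 3D scalar image and
an aligned binary volume of interest (VOI). This vignette records the
conventions the implementation commits to, why the defaults are what they
are, and what the shipped tests do and do not demonstrate.

## Coordinate and grid conventions

Arrays are indexed `[x, y, z]` with x varying fastest (R column-major
order) and z the slice axis. Voxel `(i, j, k)` (1-based) has its center at
`origin + (c(i, j, k) - 1) * spacing`; voxels are half-open boxes around
their centers. All geometry (meshes, distances, peak neighborhoods) is
computed in physical millimetres from these centers, which makes every
feature invariant under translation of the grid origin — a property the
test suite checks explicitly.

DICOM input is always rescaled by slope/intercept on load; slices are
ordered by their spatial position, never by filename, and a directory
holding more than one series is rejected rather than guessed at.
Raw-format input requires an explicit JSON sidecar (shape, dtype,
spacing) because raw data has no self-describing dialect.

## The preprocessing chain

The pipeline order is fixed: PET intensity scaling, interpolation, VOI
thresholding, range re-segmentation, outlier exclusion, discretization.
Morphology, first-order statistics and local-intensity peaks are computed
*before* discretization; the texture families and the intensity
histogram consume the discretized levels. Re-segmentation and outlier
exclusion shrink only the intensity mask — the morphological mask, and
with it every shape feature, is untouched.

Choices worth calling out:

* **Resampling alignment.** The output grid is centered on the input
  physical center ("align by center"), with `n_out = ceil(n s_in /
  s_out)` voxels per axis. This makes resampling translation-consistent.
  One visible consequence: upsampling by an even factor places no output
  center on an input center, so a single-voxel mask interpolated
  trilinearly to half spacing re-binarizes to an empty set (the
  interpolant peaks at 0.42); the empty-VOI error this raises is
  intended behaviour, not a defect.
* **Interpolators.** Nearest neighbour, separable linear ("trilinear"),
  and separable natural cubic splines. Out-of-extent queries clamp to
  the edge value. Slice-wise 2D mode never touches the z axis.
* **Mask re-binarization** after interpolation uses an inclusive 0.5
  threshold (configurable), the natural midpoint for a 0/1 field.
* **Outlier exclusion** retains values in `μ ± nσ` with population
  moments computed once on the incoming set — no iteration, so the
  result does not depend on removal order. It runs *after* range
  re-segmentation when both are enabled.
* **Discretization.** FBN: `min(⌊Nb(x − xmin)/(xmax − xmin)⌋ + 1, Nb)`;
  bins are half-open with a closed top bin, and a constant ROI collapses
  to one level. FBS anchors at the re-segmentation lower bound when one
  is configured (keeping bins comparable across subjects) and at the ROI
  minimum otherwise. The intensity-volume histogram can be discretized
  separately; without an explicit IVH rule a 1000-bin FBN fallback makes
  the fraction curves effectively continuous.
* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7). Kurtosis is excess kurtosis; "median
  absolute deviation" is the mean absolute deviation from the median,
  matching the usual radiomics label. Histogram gradients are central
  differences against a zero-padded histogram, so the end gradients are
  half the one-sided differences — the convention under which the
  canonical `H = (0, 4, 8, 4, 0)` example attains its maximum at the
  second level.

## Morphology: meshing a binary mask

No installed R package provides 3D iso-surfacing, so `build_mesh()`
implements it directly: each 2×2×2 cell of voxel centers is polygonized
by walking its face intersections at iso-level 0.5, with crossing points
at edge midpoints. On the ambiguous face configuration (equal values on
one diagonal) the inside corners are connected — for a binary field this
is exactly what the asymptotic decider chooses, since the face saddle
value is 0.5. The construction is watertight by design (every edge is
shared by exactly two triangles; the suite asserts closedness, the
isolated-voxel octahedron volume of 1/6 mm³, and Euler characteristic 0
for a torus mask).

A raw iso-surface of a binary field carries the voxelization staircase,
which barely biases volume but overestimates the surface area of smooth
bodies by roughly 8–14% at clinical PET voxel sizes. The feature
pipeline therefore applies Taubin fairing (λ = 0.5, μ = −0.53, 40
shrink/inflate passes) before measuring the mesh. The parameters were
fixed by validating mesh volume, area and sphericity against closed-form
sphere references on digitized spheres of 17–37 mm at 3.1819 × 3.1819 ×
2 mm spacing — the regime the NEMA image-quality phantom occupies —
where all values land within 5% of the analytic truth. Smoothing is a
measurement choice, not a mask edit: `smooth_iterations = 0` exposes the
raw mesh, and the oracle tests (signed-tetrahedron volume, pairwise
diameter) run against raw meshes.

The **maximum 3D diameter** is measured over ROI voxel centers rather
than mesh vertices: staircase vertices extend half a voxel beyond the
object in every axis direction, which inflates the diameter of small
spheres by 6–12% — far beyond the deviation the quantity actually has.
Voxel centers keep it within 4% on the sphere suite. **Integrated
intensity** multiplies the mean ROI intensity by the mesh volume (not
the voxel-count volume). Moran's I and Geary's C use inverse-distance
weights over all voxel pairs, computed exactly up to 20 000 ROI voxels;
larger ROIs are thinned by a deterministic stride (every k-th voxel in
array order), so no random number generator is involved and results are
reproducible by construction. Intensity peaks use a spherical
neighborhood of exactly 1 cm³ (r = 6.2035 mm), included by voxel-center
distance, clipped at the image border but not at the mask.

## Texture matrices and aggregation

All six families use Chebyshev distance 1: 13 unique directions in 3D,
4 in-plane in 2D, 26/8-neighborhoods for NGTDM/NGLDM, and 26/8-connected
zones for GLSZM/GLDZM. GLCM matrices are symmetrized by adding the
transpose before normalization (Haralick convention). The grey-level
axis always spans `1..Ng` with empty levels retained under FBN, which
affects the non-uniformity features and is the convention the reference
values assume.

GLDZM distances are city-block steps (4/6-connected) to the first voxel
outside the *morphological* mask, with boundary voxels at distance 1;
zone distance is the minimum over the zone. NGTDM and NGLDM accept
partial neighborhoods at ROI and image borders — a voxel with any valid
neighbor contributes — which is what makes the NGLDM dependence count
percentage identically 1 on any ROI, as the reference outputs print.
NGTDM coarseness is capped at 10⁶ when its denominator vanishes
(constant ROI). The NGLDM tolerance α defaults to 0 (exact level
equality).

Aggregation schemes merge *count* matrices (summing, with run/zone axes
padded to a common width) before normalization; feature averaging is the
arithmetic mean over per-matrix feature vectors, skipping slices whose
matrices are empty rather than averaging zeros in. Voxel-count
denominators (run percentage, dependence count percentage) scale with
the number of directional matrices merged, which keeps per-direction and
merged variants on a common scale. The CSV group labels reproduce the
field's customary row prefixes (`glcmFeatures2Davg`,
`GLRLMFeatures2DWmrg`, `ngtdmFeatures3D`, …); the mapping of the
"Dmrg"/"vmrg" suffixes to direction-merged and volume-merged schemes
follows the order in which the schemes are conventionally described, and
the joint-maximum values shrinking monotonically from averaged to fully
merged matrices corroborates it.

## Phantoms: what the tests show

`make_sphere()` digitizes a sphere by voxel-center inclusion — the same
semantics every mask in the package has — with a configurable
sphere-to-background contrast defaulting to 10:1, the typical NEMA fill
ratio. `make_grid()` produces seeded uniform integer grids (the RNG
state of the caller is saved and restored), and `make_digital_phantom()`
is a fixed 5×4×4 grid with an irregular mask whose feature values are
frozen against hand computation and the oracle suite. It is a synthetic
stand-in of similar scale to the published digital phantom, not a copy
of it; users who have the published benchmark files can run them through
the ordinary pipeline and compare against the published tolerance
tables.

The sphere suite demonstrates geometric fidelity of digitized masks at
clinical voxel sizes and convergence as spacing shrinks. It does not
emulate PET physics: no point-spread function, no reconstruction noise,
no partial-volume effect. Deviations reported for real scanner data
below ~2 voxel diameters are dominated by those effects and are outside
what these tests can certify.

## Determinism, problem sizes and degenerate inputs

Feature extraction is fully deterministic: identical inputs and
configuration give byte-identical CSV (floats are serialized with
round-trip `%.17g` precision; undefined values as `nan`, flagged in the
metadata file). The test suite runs on grids of at most 6×6×4 with up to
4 grey levels for the texture oracles, spheres up to 37 mm for
morphology, and N ≤ 500 for the autocorrelation oracle — sizes chosen so
every quantity can be recomputed by exhaustive enumeration.

Degenerate inputs have defined behaviour rather than silent defaults:
empty VOIs raise errors at every entry point; constant ROIs return
variance 0, entropy 0, contrast 0, a capped coarseness, a degenerate
(step) IVH curve with a warning, and `NaN` with a warning for Moran's I
and Geary's C, serialized as `nan`.

## Known limitations

* One image and one VOI per invocation; multi-series DICOM folders and
  multi-label masks are rejected, not split.
* Texture distances other than 1 and distance-weighted GLCM variants are
  not implemented.
* Lloyd-Max and histogram-equalization discretization are not
  implemented.
* RT-struct rasterization is voxel-center inclusion; partial-volume
  fractions are not computed.
* Image and mask must share one grid; no registration or resampling of
  misaligned pairs is attempted.
* Whether the "net injected activity" in a patient file is already
  decay-corrected differs between sources; a flag
  (`ActivityDecayCorrected`) declares it, defaulting to correction at
  the stated injection time.
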