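---
title: "Methods: multimodal reconstruction for correlative array tomography"
author: "icatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal reconstruction for correlative array tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices in
`icatr`. Code chunks are illustrative and not evaluated during build.

## Coordinate conventions and the transform model

All geometry lives in a single **world frame**: the high-magnification
EM pixel grid at 5 nm/px, x to the right, y down, with 0-based pixel
*centers*. Every other modality is attached to this frame by a planar
affine transform `p' = A p + t`, stored as an `affine2d` with row-major
coefficients `(a11, a12, tx, a21, a22, ty)`. Compositions, inverses and
similarity constructors (`affine_compose`, `affine_invert`,
`affine_similarity`) are exact closed-form operations; all solvers below
estimate either the full 6-parameter affine or restricted 2-parameter
(translation) and 4-parameter (rotation-free "rigid", i.e. linearized
similarity) models.

Pixel sizes in the reference geometry: EM high 5 nm, EM low 38 nm
(ratio 7.6), FM about 130 nm, slide overview 7 µm. An FM mosaic with
20 % tile overlap determines the usable EM field width,
`em_field_width(w_fm, 0.2) = w_fm * (1 - 2*0.2)`, about 140 µm for a
233 µm FM field.

## Feature extraction and matching

Stitching and serial alignment rest on a deterministic, self-contained
multi-scale feature pipeline (`extract_features`):

- a difference-of-Gaussians pyramid with keypoints at scale-space
  extrema, 3D quadratic sub-pixel refinement;
- a contrast threshold (default `0.01`) and an edge-response test
  (principal-curvature ratio 10) prune unstable points;
- dominant gradient orientation assignment and a 128-dimensional,
  unit-normalized gradient-histogram descriptor.

`match_features` pairs descriptors under Lowe's ratio test (0.8), then
filters with RANSAC (fixed internal seed 1234, 1000 iterations, 3 px
inlier radius, minimum 5 inliers) under a user-chosen model. Everything
is deterministic for fixed inputs.

One deliberate deviation in the cross-spatial step
(`register_lowmag_to_montage`): the low-magnification tile and the
montage composite are band-limited, so their DoG contrast is genuinely
lower and the keypoint threshold is halved to `0.005`; and the RANSAC
model is `"rigid"` rather than `"affine"` because the physical
low-mag-to-world map is a similarity and the 2-point minimal sample is
far more robust at the small match counts coarse imagery yields.

## The sparse regularized solver

`solve_montage` and `solve_volume` share one linear least-squares core.
For each tile a parameter vector (2, 4 or 6 entries by model) describes
its transform; each point correspondence between tiles contributes two
rows linking both tiles' parameters; each tile also receives weak
regularization rows (`lambda`, default `0.005`) pulling it toward its
initialization (nominal stage position, or montage-times-rough-z for
the volume). Gauge freedom is removed by eliminating one anchor tile's
parameters. The system is assembled as a `Matrix` sparse matrix and
solved via the normal equations with a Cholesky factorization.

The test suite replicates this construction densely with
`qr.solve` oracles and requires coefficient-wise agreement below 1e-8
for all three models, including weighted and rank-deficient cases.
Residual RMS per match set is attached to the solution for QC.

## Cross-modal (CL) registration

The CL acquisition burns a grid of electron-beam spots into the FM
camera frame. `detect_spots` localizes spots with a 2D Gaussian `nls`
fit per candidate window; `nls` is run with `warnOnly = TRUE` followed
by explicit validation (positive width and amplitude, center inside the
window, residual RMS under 10 % of peak) because `nls` *errors* on
zero-residual noise-free data — a centroid fallback covers rejected
fits. `match_grid` then pairs detected spots to the commanded beam grid:
both point sets are normalized (centroid, RMS scale; principal-axis
rotation only when *both* sets are anisotropic, since rotating a square
grid's degenerate principal frame mispairs systematically), mutual
nearest neighbors seed the pairing, and an exhaustive mini-RANSAC over
all 2-subsets selects the similarity hypothesis with the largest
re-paired consensus. The capture range for a square 3×3 grid is about
±0.15 rad of rotation; within it, recovery is below 0.1 FM px at
SNR 50, tolerant of one missing and one spurious spot.

## Cross-spatial overlay

`register_lowmag_to_montage` renders the stitched high-magnification
tiles into a composite at the low-magnification pixel scale over the
tile's stage footprint (plus 8 px margin), matches features as above,
and fits the low-mag-to-world affine. A guard rejects fits whose
singular values deviate more than 5 % from the nominal pixel-size ratio
(7.6), which catches spurious consensus. Composing with the CL transform
(`overlay_chain`) yields FM-to-world: accurate to about one
low-magnification pixel *inside* low-mag footprints and degrading where
extrapolated — which is why gaps between low-mag fields should be
avoided at acquisition time.

## Serial-section alignment and the depth-search window

`rough_align_z` chains feature-based registrations between consecutive
*present* sections (optionally downsampled) to initialize each section
in the first section's frame. Fine alignment gathers cross-section
matches under a **depth-search plan**: all section pairs at z distance
up to `depth`. A run of `k` consecutive missing sections needs
`depth >= k + 1` to connect its neighbors — two consecutive discarded
sections (z = 9, 10 in the reference series) force depth 3, matching
z = 8 directly to z = 11. `min_connecting_depth` computes the minimal
window from the present-section set; `solve_volume` reports a
disconnected match graph by naming the weakly connected section groups.
`export_stack` renders the aligned volume to a multi-plane TIFF with one
plane per *present* section (63 of 66 in the reference series).

## Synthetic generators as study conditions

All validation runs on simulators with known ground truth:
band-limited tissue textures with nuclei and membranes
(`make_tissue_texture`), tile grids with stage jitter, shading and
noise (`simulate_tileset`), low-magnification proxies
(`simulate_lowmag_tile`), CL spot frames (`simulate_cl_acquisition`),
slide overviews (`simulate_slide_overview`), and drifting,
decorrelating serial stacks with discarded sections
(`simulate_serial_stack`). Generator defaults are fixed study
conditions; tests recover the hidden parameters rather than tuning the
generators to the estimators. Seeds are fanned out per component with
`derive_seed` and never disturb the caller's RNG state.

## Limitations

- The feature pipeline targets textured EM imagery; featureless or
  periodic content defeats it (as it would any correspondence method).
- The "rigid" model is a linearized similarity, not a hard rotation
  constraint; strongly sheared solutions are excluded only by the
  regularization and, in the cross-spatial step, the scale guard.
- CL grid matching assumes a roughly known scale between FM and EM-low
  frames and rotations within the square-grid capture range.
- Volume alignment models each section as rigid-to-affine in-plane;
  nonlinear section distortions are out of scope.
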