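---
title: "Segmenting the coronary artery wall in CTA: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the coronary artery wall in CTA: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Contrast-enhanced coronary CT angiography (CCTA) shows the blood-filled
lumen of the coronary arteries at high contrast, but the vessel *wall* — the
tissue between the inner (lumen) boundary and the outer vessel boundary,
where atherosclerotic plaque lives — is thin and poorly contrasted. A
healthy wall is about 0.75 mm thick at a voxel size of roughly
0.3–0.4 mm, and the outer boundary often abuts myocardium of nearly
identical attenuation. Manual wall delineation is slow and has high
inter-observer variability; `coroseg` implements an automatic pipeline that
needs only two clicked seed points per artery.

## The pipeline

The framework runs in a fixed stage order:

1. **Vesselness filtering.** A multiscale Hessian (Frangi) filter scores
   every voxel for tube-likeness. At each Gaussian scale the
   second-derivative (Hessian) eigenvalues $|\lambda_1| \le |\lambda_2| \le
   |\lambda_3|$ are combined into the standard line measure using the
   plate/line ratio $R_A = |\lambda_2|/|\lambda_3|$, the blob ratio
   $R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$, and the structureness
   $S = \lVert H\rVert_F$; responses with the wrong eigenvalue signs for a
   bright-on-dark tube are zeroed, and the maximum over scales is kept.
2. **Robust lumen initial contour (S1).** Seeded region growing is applied
   *independently* to the HU image (which admits everything blood-connected
   to the seed, including the aorta) and to the vesselness image (which
   admits tube-like structure, including false enhancements such as sheets
   and vessel-like artifacts), and the two binary masks are intersected.
   Each filter cancels the other's failure mode.
3. **Lumen level set (S3).** An edge-based level set expands S1 outward to
   the lumen boundary, guided by a feature (speed) image — the sigmoid of
   the Gaussian gradient magnitude — that is ~1 in homogeneous tissue and
   ~0 at strong edges.
4. **Outer initial contour (S2).** The final lumen is extended by **5.5 mm**
   of *restricted* (geodesic) morphological dilation, sized to enclose even
   severely thickened walls. Perivascular fat, identified as voxels with
   negative HU, blocks the propagation, so wherever fat sheathes the artery
   the dilation already hugs the true outer boundary.
5. **Vessel level set (S4).** A second level set shrinks S2 inward to the
   outer wall boundary.
6. **Wall.** `vessel := S4 ∪ S3` (containment enforced) and
   `wall := vessel \ lumen`, voxel-exact.
7. **Visualization products.** The zero-level surfaces are triangulated
   (V1/V2), a medial-axis centerline with orthonormal frames is extracted
   from the lumen (V3), and the volume and masks are straightened by curved
   multiplanar reformation (CMPR, V4); radial longitudinal sections and a
   per-cross-section wall-thickness profile are computed from the
   straightened grids. Five radial sections imply the conventional 36°
   angular gap; 20 sections (9°) are supported for finer review protocols.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| vesselness scales | 0.5–2.5 mm | Gaussian scales covering coronary calibers ≥ 2 mm |
| Frangi α, β | 0.5, 0.5 | plate/blob sensitivities (original formulation) |
| Frangi c | adaptive | half the max Hessian Frobenius norm, shared across scales |
| HU growth window | [175, 800] HU | contrast-filled lumen |
| vesselness threshold | top 5 % of nonzero | vessel-like structure |
| dilation distance | 5.5 mm | outer initial contour halo |
| fat threshold | 0 HU | dilation barrier (fat is negative) |
| gradient σ (lumen / vessel) | 0.5 / 0.5 mm | feature-image derivative scale |
| sigmoid center β | adaptive | gradient quantile in a one-sided shell outside the initial contour: q90 (lumen), q50 (vessel) |
| propagation, curvature, advection | ±0.5, 0.4, 2 (lumen) / 0 (vessel) | level-set term weights |
| centerline resample step | 0.25 mm | sub-voxel CMPR sampling |
| CMPR half-width / in-plane step | 10 / 0.2 mm | straightened cross-section grid |
| QC caliber | 2.0 mm | spans below this area-equivalent diameter are flagged |

Two calibration choices deserve explanation, because they were genuinely
open design decisions settled on phantoms:

* **One-sided adaptive sigmoid.** The sigmoid center is taken from the
  gradient statistics of a thin shell *outside* the initial contour, which
  is where the stopping boundary lies for both evolutions. A two-sided
  shell would be dominated by the far stronger lumen edge when calibrating
  the outer-wall stage (the wall is only ~2 voxels thick).
* **Propagation-only outer evolution.** Across a thin wall the gradient
  magnitude rises monotonically from the fat side to the lumen edge: the
  outer boundary is a *shoulder* of the gradient profile, not a local
  maximum. An advection term therefore drags an inward front straight
  through the wall to the lumen edge — the classical observation that
  maximum-gradient points match neither boundary. The outer evolution
  instead uses pure feature-weighted propagation with a sharp sigmoid
  centered at the fat-side background gradient level (its median), so the
  front freezes where the gradient first rises above background — i.e., at
  the shoulder base. The lumen boundary *is* a gradient peak, so the lumen
  stage keeps the advection term, which pins the front sub-voxel.

## Numerics

* **Level sets** evolve a signed-distance function (negative inside) with
  Godunov upwinding for the propagation term, central differences for the
  feature-weighted mean-curvature term, upwind advection along
  $-\nabla f$, CFL-bounded time steps, and a narrow band (6× min spacing)
  rebuilt every iteration. Every 20 iterations the function is re-distanced
  from its current mask (mask-preserving reinitialization). Evolution stops
  when the RMS per-iteration change drops below 10⁻³ or at 500 iterations
  (the result is then flagged, not rejected). Voxels with φ = 0 exactly are
  foreground.
* **Restricted dilation** is a geodesic shortest-path distance on the
  5×5×5 gcd-reduced lattice neighbourhood (chamfer error ≈ 2 % of
  Euclidean) with physical edge lengths; long moves are admitted only if a
  monotone staircase of unit steps stays inside the domain, so the dilation
  cannot tunnel diagonally through a one-voxel fat barrier. Half a voxel is
  added to the distance threshold to account for measuring lattice
  distances between voxel centers rather than from the region surface.
* **Meshes** come from marching tetrahedra (six tetrahedra per cell sharing
  the main diagonal, which makes face diagonals agree between neighbouring
  cells), with vertices deduplicated per lattice edge — watertight by
  construction — and oriented by the local field gradient.
* **Centerlines** ride the interior distance-transform ridge: Dijkstra
  between the two seeds with edge costs inversely weighted by the local
  inscribed radius cubed, then Gaussian smoothing along arc length (capped
  at 0.3 mm deviation from the raw medial path) and uniform resampling at
  0.25 mm. Frenet–Serret normals are used where curvature exceeds
  10⁻⁴ mm⁻¹; straighter stretches fall back to rotation-minimizing
  parallel transport (the Frenet frame is undefined at zero curvature), and
  a continuity correction forbids antipodal frame flips. CMPR uses these
  transport-corrected frames to avoid in-plane spinning along straight
  segments.
* **CMPR of masks** resamples the mask's signed-distance field with linear
  interpolation and thresholds at zero: the result is still a binary mask
  but carries the sub-voxel boundary position instead of the voxel
  staircase. Nearest-neighbour sampling remains available.
* **Anisotropy** is never resampled away: every mm-parameterized operation
  (kernels, distances, dilation, CMPR) converts to per-axis voxel units
  itself. Voxel indices are 0-based, a voxel's coordinate is its center,
  and all geometry is in mm.

## The phantom generator

Because in-vivo wall ground truth requires an expert consensus reading, the
package validates against synthetic vascular phantoms with *analytic*
ground truth. `make_phantom()` rasterizes a tube along a parametric curve
(line, circular arc, or helix): voxels are classified by distance to the
curve against lumen/outer radius profiles; plaques narrow the lumen and
thicken the wall under a raised-cosine bump and carry soft (50 HU),
calcified (800 HU) or mixed attenuation; a perivascular fat sheath
(−80 HU) surrounds the wall (the typical coronary environment — it also
wraps the clipped tube ends, as fat runs on along a real artery); the
remainder is myocardium (40 HU). Boundary voxels are supersampled 3× per
axis and averaged (partial volume), then optional motion blur (a local
anisotropic Gaussian blend over an arc-length window) and seeded Gaussian
noise (default σ = 20 HU) are applied. Ground-truth masks are noise-free
voxel-center rasterizations; analytic volumes are arc-length integrals of
$\pi r(s)^2$. Confounder helpers add a bright ribbon near the vessel
(vesselness bait) or a parallel vein at wall-like HU, leaving the truth
masks untouched.

The motion-blur magnitude for the robust-initialization benchmark
(σ = 1.5 mm over a 5 mm window with a 0.75 mm transition) was chosen
empirically as the weakest blur that reliably halts a naively initialized
level set: the blur drops the in-gap lumen to ~150 HU, creating an
axial pseudo-edge at the gap entrance. The framework's intersection-based
initial contour, seeded at both ends, still covers the artery on either
side of the gap, so its refinement stays local; a single-seed sphere
baseline — given a deliberately *stronger* balloon force so it can traverse
clean lumen — terminates at the artifact.

What passing these tests does **not** show: phantoms have piecewise-constant
tissue classes, no beam hardening, no calcium blooming, no cardiac-phase
misregistration, and a single unbranched vessel. Results on them bound the
geometric fidelity of the machinery, not clinical performance.

## Evaluation metrics

Pooled over structures/plaques $i = 1..n$ with test masks $V_t$ and
reference masks $V_r$:

$$\mathrm{DICE} = \frac{2\sum_i |V_{t_i} \cap V_{r_i}|}{\sum_i (|V_{t_i}| + |V_{r_i}|)} \times 100\,\%$$

volume mean squared error $\frac{1}{n}\sum_i (v_{t_i} - v_{r_i})^2$ (volumes
in mm³; reported in the units the metric is conventionally tabulated in),
relative volume error $\sum_i |v_{t_i}-v_{r_i}| / \sum_i v_{r_i} \times
100\,\%$, precision $\sum|V_t \cap V_r|/\sum|V_t|$ and sensitivity
$\sum|V_t \cap V_r|/\sum|V_r|$, plus Bland–Altman bias and 1.96 SD limits
and a plaque-length-quartile pooling helper. All five pooled metrics are
tested for exact agreement with a brute-force voxel-loop oracle.

## Problem sizes and expected accuracy

The validation suite uses phantoms of roughly 56–91 voxels per axis at
0.3–0.4 mm spacing (a single-artery field of view), where a full pipeline
run takes ~25 s on one CPU core. On the curved 50 %-stenosis phantom the
pipeline reaches lumen/vessel/wall DICE of about 97/98/94 % noise-free and
96/97/93 % at σ = 20 HU; analytic geometry (cylinder volume, sphere mesh
area, helix curvature, torus centerline length, annulus wall thickness) is
recovered within 1–3 %. These numbers are recomputed from scratch by
`scripts/acceptance.R` and asserted by the test suite; the vignette states
no result the code does not itself compute.

## Known limitations

* The outer-wall stage relies on the fat barrier for its tight
  initialization; where the artery is fully embedded in myocardium the
  10 HU wall/myocardium contrast is below what edge-based evolution can
  resolve, and the segmentation will inherit the dilation halo there.
* A touching parallel vein (surface gap 0 mm) merges with the outer wall in
  the vesselness and HU images and degrades the outer boundary — kept as a
  documented expected-failure fixture.
* Lattice effects bound boundary accuracy at ~half a voxel; all stated
  tolerances are honest measurements at 0.3–0.4 mm spacing, not asymptotic
  claims.
* The DICOM reader supports one uncompressed little-endian series per
  directory; compressed transfer syntaxes are rejected with an explicit
  error.
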