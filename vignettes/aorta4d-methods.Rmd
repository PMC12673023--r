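---
title: "Quantifying aortic biomechanics from 4D segmentations: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic biomechanics from 4D segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`aorta4d` measures thoracic aortic biomechanics from time-resolved 3D binary
lumen segmentations (one mask per cardiac phase, typically 30 phases at
~1 mm isotropic voxels). Its headline quantities are:

* **3D distensibility** of the ascending (AAo) and descending (DAo) aorta:
  `(max_t V(t) - V(0)) / (V(0) * PP)`, with `V(t)` the segment volume,
  phase 0 the end-diastolic reference, and `PP` the brachial pulse pressure.
  Reported in 1e-3/mmHg.
* **Motion-corrected 2D distensibility** of the mid-ascending and
  mid-descending planes: the same ratio on the cross-sectional area of a
  plane that is *tracked* through the cycle rather than held fixed in space.
* **Longitudinal strain** of the AAo:
  `100 (L(t) - L(0)) / L(0)`, with `L(t)` the centerline length from the
  aortic annulus to the brachiocephalic trunk (BCT).
* **Mean surface displacement** at four anatomical planes (sinotubular
  junction, mid-AAo, mid-DAo, diaphragm), from non-rigid registration of the
  end-diastolic lumen surface to every other phase.
* **Aortic tortuosity index (ATI)**: centerline arc length from the
  sinotubular junction to the diaphragm divided by the chord between them.

Subject-level values are maxima over phases (earliest phase on ties), with
end-diastole defined as the first reconstructed phase. The package also ships
a deforming-aorta phantom generator with analytic ground truth, a cohort
simulator calibrated to published group summaries for healthy volunteers and
Marfan patients (native root and post-root-replacement), and a statistics
stage (one-way ANOVA with a 0.005 significance gate, Tukey HSD, univariate to
multivariate regression with VIF screening, Pearson correlation).

# Pipeline

Given a validated series, annotated landmarks (seven world-mm points:
annulus, STJ, mid-AAo, BCT, LSA, mid-DAo, diaphragm) and a blood pressure,
`compute_subject()` runs:

1. **Validation** — every phase must hold exactly one 26-connected component
   with a clean 1-voxel margin. Failures are reported, never repaired:
   silently keeping the largest component would hide segmentation faults
   that warrant exclusion.
2. **End-diastolic centerline** — Dijkstra shortest path between the STJ and
   diaphragm seeds on the foreground voxel graph, with edge cost
   step/(1e-3 + boundary distance) so the path follows the medial ridge;
   straight extension to the annotated annulus; cubic smoothing-spline fit
   (one degree of freedom per 7 mm of length) resampled at 0.5 mm; then
   **centroid re-centering**: each sample is replaced by the centroid of the
   perpendicular lumen cross-section and the spline refit, twice. The raw
   voxel path meanders within a voxel; re-centering brings positions to
   ~0.1 mm and tangents to ~0.3 degrees on phantoms, which matters because a
   plane normal that is off by 7 degrees inflates a cross-sectional area by
   about 1% — on the same order as the systolic area change being measured.
3. **Displacement field** — two-stage non-rigid registration of the
   decimated (1500-point, farthest-point-sampled) end-diastolic surface to
   each phase, detailed below.
4. **Tracked planes and areas** — each anatomical plane is displaced by the
   mean displacement of surface points in a +-2.5 mm band and re-oriented by
   the best-fit (Kabsch) band rotation, adopted only when it reduces the
   band residual by at least 5% — on bands whose motion is dominated by
   dilation, an unconditional rotation fit chases sampling jitter. Areas are
   sampled on the lightly smoothed mask (sigma 0.7 voxel) with trilinear
   interpolation at the 0.5 level, flood-filled from the plane center, and
   averaged over five parallel sections (+-5 mm along the normal).
5. **Segment volumes** — foreground is binned by nearest-centerline arc
   length (unambiguous and exactly partition-additive in a curved vessel,
   unlike clipping half-spaces at two non-parallel planes), with the
   coordinate extrapolated linearly beyond the centerline ends. Volumes are
   counted with 2x sub-voxel supersampling of the smoothed mask. AAo bounds:
   transported annulus to transported BCT; DAo: LSA to diaphragm.
6. **Per-phase centerlines for strain** — re-extracted per phase with seeds
   and the annulus transported by the displacement field, re-centered, with
   the transported BCT projected onto them.

# The registration model

The displacement engine is coherent point drift (CPD): the moving
(end-diastolic) point set is treated as Gaussian-mixture centroids displaced
by a smooth field and fitted to the target phase by EM; the field is
expanded in the leading eigenmodes of a Gaussian coherence kernel (low-rank
CPD). Registration runs in two stages:

* **Stage 1 (stiff vector field)**: kernel width `beta = 25 mm`,
  `lambda = 2`, 300 modes. A vessel surface is locally a cylinder, so
  point-set correspondence alone only determines the *normal* component of
  motion (the aperture problem); a translation of the root perpendicular to
  its axis would otherwise be recovered at only ~2/pi of its magnitude.
  Wide-kernel coherence resolves this: the smoothest field consistent with
  the normal-component evidence is the true bulk motion.
* **Stage 2 (normal refinement)**: displacement along the reference surface
  normals only, kernel width 10 mm, 100 modes, `lambda = 4`. Lumen dilation
  is a normal motion; restricting the fine scale to the normal direction
  removes the tangential correspondence jitter (~1 mm) that two
  independently decimated point sets otherwise produce. At 1 mm voxels this
  recovers a 1.5 mm radial inflation within +-0.3 mm at ~97% of surface
  points on a cylinder phantom.

Phases are registered independently from phase 0 (no sequential chaining, so
no drift accumulation), with the EM warm-started from the neighbouring
phase's coefficients — a pure convergence aid that does not change the
fixed point. Bit-identical masks (diastole in the phantom, where the
waveform is exactly zero) share one registration deterministically.
Surfaces for registration are extracted by marching tetrahedra on the
mask smoothed at sigma = 1.0 voxel; the shared smoothing bias cancels in
displacement differences, and the heavier smoothing (compared to 0.8 for
geometry) lowers the correlated staircase noise that otherwise limits
per-point recovery.

Displacements at arbitrary points (landmark and seed transport) are
interpolated from the decimated points with a normalized Gaussian kernel of
width 2 mm — narrow, so that the annulus (which sits on the moving end face)
is not dragged by adjacent wall points whose tangential motion is invisible.

**Level transport.** Interior anatomical levels (BCT, LSA, diaphragm) are
defined by structures outside the aorta; sliding of such a level *along* the
vessel is exactly the aperture-null direction that surface registration
cannot observe. These landmarks are therefore transported with only the
tangent-orthogonal component of the local field: they follow the vessel's
lateral motion but keep their arc-length station. The annulus, an end-face
feature whose motion the registration observes directly, receives the full
field. On phantoms this removes a ~1% per-phase wobble in segment-volume
bounds that would otherwise be amplified ten-fold in the distensibility
ratio.

# The phantom

`phantom_spec()`/`build_phantom()` synthesize a deforming aorta with
analytic ground truth: a straight proximal root (25 mm), a semicircular
arch (radius 40 mm), and a straight descending limb (100 mm); lumen radius
15 mm (ascending) tapering to 11 mm between the BCT and LSA landmarks. The
annulus-to-BCT length is 79.5 mm at end-diastole, matching the published
healthy mean. The whole geometry is tilted (4 and 6 degrees about two axes):
real aortas are oblique to the scanner grid, and an exactly grid-aligned
straight limb is a pathological special case in which voxelization error is
coherent along the vessel and does not average out.

Three deformation modes share one systolic waveform
`f(t) = sin^2(pi t / T_sys)` for `t < T_sys` (default 0.35), zero in
diastole:

* **radial dilation** `r(s, t) = r0(s) (1 + a(s) f(t))`;
* **longitudinal stretch**: arc-length reparametrization of the
  annulus-to-BCT segment anchored at the BCT, so `L(t) = L0 (1 + eps f(t))`
  exactly. Anchoring at the arch apex instead would give a peak strain of
  `eps * s_apex / L0 != eps`, contradicting the intended ground truth.
  Material sliding along a locally cylindrical tube is unobservable from
  the surface; what the pipeline (and a segmentation-based method on real
  data) actually measures is the motion of the annulus end face, which this
  mode displaces by `eps f L0` along the root axis.
* **root displacement**: translation along +y (perpendicular to the arch
  plane) weighted by `w(s)`, linear from 1 at the annulus to 0 at the arch
  apex. The perpendicular direction keeps centerline arc length unchanged
  to first order, so the displacement mode does not contaminate the strain
  ground truth; a root translation along the vessel axis would add several
  percentage points of apparent strain and make the closed forms for the
  two modes inseparable.

Masks are voxelized as the union of spheres along the deformed centerline
(0.5 mm arc step) with both ends cut flat; rounded end caps would add a
`(2/3) pi r^3 (1+a f)^3` term to segment volumes and bias 3D distensibility
~6% away from its closed form. Peak closed forms: AAo 3D distensibility
`((1+a)^2 (1+eps) - 1)/PP` (volume scales as r^2 L), DAo and both 2D
distensibilities `((1+a)^2 - 1)/PP`, strain `100 eps`, and ring-mean surface
displacement `mean_phi |dr n(phi) + w d y|` per plane. With 30 phases the
waveform grid peaks at f = 0.994, so measured peaks sit ~0.6% below the
f = 1 closed forms — well inside the validation tolerances.

What the phantom does *not* emulate: sinus-of-Valsalva geometry and branch
vessels, through-plane twist, segmentation errors beyond voxelization, mode
timing offsets (all modes peak together; no per-mode timing is reported for
real aortas), and image-contrast effects — the generator produces masks, not
images. Passing phantom tests therefore demonstrates correct measurement of
idealized tube deformation at scanner resolution, not robustness to
real-world segmentation quality.

# Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) validates at the
study's working resolution, 1 mm / 30 phases:

* a 3x3 amplitude grid `a in {0.05, 0.10, 0.15}` x `eps in {0, 0.10, 0.15}`
  (no root displacement), asserting 3D and 2D distensibilities within 5% of
  their closed forms and strain within 0.7 percentage points — nine full
  subjects, about one minute each;
* a root-displacement sweep `d in {5, 10}` mm at `a = 0.10`, asserting the
  peak STJ mean displacement within 0.5 mm of `w(s_STJ) d`;
* a zero-deformation subject (noise floor: distensibilities <= 0.3e-3/mmHg,
  strain <= 0.5 pp, displacement <= 0.3 mm);
* geometry, registration and statistics oracles (closed-form areas, volumes
  and tortuosity; identity/translation/rigid-equivariance registration;
  brute-force ANOVA/Tukey/Pearson/OLS agreement and CI coverage);
* an exactness check that halving pulse pressure exactly doubles every
  stored distensibility (pure powers of two commute with IEEE rounding).

The displacement-mode sweep is run separately from the amplitude grid
because the closed forms being tested are per-mode: with both stretch and
root displacement active, the annulus motion and the (second-order)
arc-length change of a perpendicular translation mix into strain and STJ
displacement by design of the physics, not by error of the method.

Unit tests use a scaled-down phantom (1.5 mm voxels, 6 phases, smaller
geometry) so the whole non-acceptance suite stays fast; every quantitative
claim made at coarse resolution is re-asserted at full resolution in the
acceptance suite.

# Numerical choices

* **Areas and volumes on a smoothed mask.** A binary mask's voxel count for
  a tube has a deterministic lattice bias that oscillates with radius by
  +-1-2%; between end-diastole and peak this bias difference is amplified
  ten-fold in the distensibility ratio. Areas/volumes are therefore
  measured on the Gaussian-smoothed indicator (sigma 0.7 voxel) whose
  0.5-level tracks the coverage-0.5 contour; sampling uses irrational
  sub-step offsets (rotated per slice for volumes) so counting error does
  not cohere on symmetric alignments; plane areas average five parallel
  sections over +-5 mm.
* **Sub-sample landmark projection.** Landmarks project to the exact foot
  point on the centerline polyline; nearest-sample projection quantizes
  lengths to the 0.5 mm resampling step and biases the max-over-phases
  upward.
* **Ties.** Earliest phase wins peak ties; landmark projection ties break
  toward smaller arc length.
* **Degenerate inputs** are hard errors with tagged messages: empty or
  non-binary masks, disconnected seeds, planes outside the lumen,
  coincident tortuosity landmarks, zero baselines, non-positive pulse
  pressure.

# Cohort simulator and statistics stage

`simulate_cohort()` draws per-subject metric panels for three groups
(healthy n=47, native n=51, root-replaced n=33 by default) from
mean-calibrated truncated normals: at the published group dispersions a
plain normal draw can go negative (e.g. mean 1.4, SD 0.7), and naive
truncation would shift the mean by nearly 3%, so the location parameter is
solved so that the truncated mean hits the target (verified within 2% at
n = 10^4). Two structural features give the statistics stage a known ground
truth: age and root-diameter effects on AAo 3D distensibility in the native
group (-0.06 per year, -0.10 per mm), and group-specific correlations
between 2D and 3D distensibility (0.39-0.90). The statistics functions
delegate to base R (`aov`, `TukeyHSD`, `lm`, `cor.test`, `chisq.test`
without continuity correction) and `car::vif`; collinear predictors are
dropped highest-VIF-first until all VIF <= 5 — the exclusion order is a
package convention, as is exposing the 0.005 gate as a parameter. Missing
covariates are an error, not a silent listwise deletion.

# Known limitations

* Tangential motion on a locally cylindrical surface is unobservable in
  principle for any segmentation-surface method. Consequences: (i) material
  sliding (e.g. circumferential stretch) is not part of the reported
  displacement; (ii) the registration solution is unique only up to
  tangential sliding, so per-point equivariance under a rigid transform of
  a *deformed* target holds only for the determined (normal + bulk) part;
  (iii) around the dilating arch, density matching genuinely prefers a
  small tangential redistribution (~1-2 mm), which is why interior level
  landmarks are transported without their tangential component.
* Accuracy beyond ~1500 decimated points is limited by surface voxelization
  noise, not sampling: denser decimation past the operating point does not
  improve (and can slightly worsen) per-point recovery.
* When strain is large, coherent stage-1 motion near the annulus bleeds a
  few millimetres into the STJ displacement band (the material there truly
  moves tangentially; the ground-truth convention counts only radial and
  root-translation motion). STJ displacement is therefore validated in the
  root-displacement sweep, where the quantity is well-defined.
* Brachial pulse pressure overestimates central pulse pressure, so absolute
  distensibilities are systematically conservative; this affects real-data
  interpretation, not phantom validation.
* Only axis-aligned (RAS, positive-diagonal) NIfTI geometries are accepted;
  oblique acquisitions must be resampled upstream.
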