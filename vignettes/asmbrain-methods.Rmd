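---
title: "Active-shape quantification of brain perfusion SPECT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-shape quantification of brain perfusion SPECT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmbrain)
```

## The problem

Regional cerebral blood flow (rCBF) SPECT with a flow-trapped tracer such as
99mTc-HMPAO yields a 3D count volume in which cortical tracer uptake is a
surrogate for perfusion. Clinical reading is usually visual; `asmbrain`
implements a fully automated quantification: it delineates the brain surface
with a statistical shape model, projects maximal cortical counts onto a
fixed set of surface sample points, normalizes them to a reference region,
and aggregates them into lobar means, left-right asymmetry indices and a
global cortical index. Applied to a group of normal scans, the same
machinery produces a normal-value database against which a patient scan can
be z-scored point by point and region by region.

Because absolute flow (ml/100 g/min) is not available from a relative count
volume, everything is expressed in percent of a reference value.

## The point-distribution shape model

The brain surface is represented by $L = 546$ corresponding landmarks
arranged as closed rings in sagittal planes (26 rings of 21 points). A
training group of delineated surfaces is brought into a common frame by
generalized Procrustes alignment (translation, rotation and isotropic
scale), and the flattened landmark vectors $x_i \in \mathbb{R}^{3L}$ are
decomposed by PCA:

$$x \approx \bar{x} + P\,b,$$

where the columns of $P$ are the eigenvectors ("modes") of the sample
covariance (denominator $n-1$) with the $K = 5$ largest eigenvalues
$\lambda_1 \ge \dots \ge \lambda_K$, and $b$ are the mode coefficients. New,
plausible brain shapes are synthesized by varying $b$; a shape is considered
plausible when $|b_k| \le m\sqrt{\lambda_k}$ with $m = 3$.

Design choices at points the method leaves open:

* **Alignment class.** Full similarity Procrustes (scale removed) is the
  default, because the surface fit estimates scale and pose per scan anyway;
  `align_shapes(scale = FALSE)` keeps overall size as a mode instead.
* **Covariance normalization** uses the standard $n-1$ denominator.
* **Mode sign** is fixed by making each mode's largest-magnitude component
  positive, for reproducibility.
* **Procrustes convergence**: maximum point displacement below $10^{-6}$
  (in the unit-size frame) or 100 sweeps; the final frame is anchored to the
  first shape's orientation so results are deterministic.

`shape_model()` is the estimator entry point and returns an S3 object with
`print`, `summary`, `coef` (eigenvalues), `predict`/`synthesize_shape`,
`simulate` and `plot` methods; `project_shape()` is the inverse operation
(pose + coefficients of an observed landmark set, optionally clamped and
weighted).

## The five analysis steps

1. **Rotation.** The in-sagittal-plane orientation is estimated as the first
   principal axis of the above-threshold voxel coordinates projected to the
   y-z plane, plus a configurable offset angle (`estimate_rotation`). The
   threshold is 30% of the 99.5th-percentile intensity. The offset's
   anatomical zero is a site calibration constant; the estimator itself is
   equivariant (rotating the volume by $\theta$ shifts the estimate by
   $\theta$). `rotate_volume` resamples each sagittal slice; it uses bicubic
   (Catmull-Rom) interpolation because linear resampling floors the
   rotate/derotate round-trip error at about 2% of the maximum intensity at
   2 mm voxels, while bicubic brings it to about 0.2%.
2. **Delineation.** `fit_active_shape` alternates a boundary search along
   the current surface normals with a constrained model projection. The
   boundary criterion along each profile (default $\pm 15$ mm, 1 mm step) is:
   intensity inside a fraction interval $[0.25, 0.85]$ of the robust maximum
   *and* the steepest outward intensity fall of at least 2% of the robust
   maximum per mm; the winning candidate is refined to sub-step precision by
   a parabola through the gradient samples. Points with no qualifying
   candidate keep their position with confidence 0 and enter the projection
   with weight 0.1 (moved points weigh 1). Three robustness measures,
   standard for active-shape fitting, stabilize the iteration: the first 10
   iterations fit the similarity pose only (modes held at zero); proposals
   moving more than 3 robust SDs of the current offsets are treated as
   unmoved (this gates out the cerebellar-occipital crease, where profiles
   cross two structures); and the projection is re-solved once with Cauchy
   weights on its residuals. Convergence is a mean landmark movement below
   0.1 mm; non-convergence is reported, never raised.
3. **Normalization.** Three references are computed and all reported in
   parallel: the mean of the cortical (surface-projection) samples over the
   cerebellar points; the cerebellar maximum (mean of the hottest cerebellar
   voxel and its 26 neighbours — among equally hot voxels the one with the
   largest neighbourhood mean, then the lowest index, a deterministic
   tie-break); and the mean over all non-cerebellar surface samples. The
   volume is scaled so the reference reads 100%. "Cortical part of the
   cerebellum" is operationalized as the surface-projection samples over
   cerebellar points, consistent with how every other cortical value is
   sampled.
4. **Cortical projection.** 3010 sample points are interpolated from the 546
   landmarks by deterministic barycentric subdivision of the surface
   triangulation (vertices, then face centroids, then edge midpoints in a
   canonical order, truncated to the exact count). Each point takes the
   maximum of trilinear samples along its inward normal from the surface to
   a depth of 9% of the brain length (anterior-posterior extent of the
   fitted surface) — about 15 mm for a 167 mm brain — in steps of at most
   1 mm; ties go to the sample nearest the surface. Regional means are
   arithmetic means over each atlas label; the asymmetry index of a paired
   region is
   $100\,(\mathrm{CBF}_{sin} - \mathrm{CBF}_{dx}) / \tfrac12(\mathrm{CBF}_{sin} + \mathrm{CBF}_{dx})$.
   The symmetric-mean denominator is our choice where the exact published
   form is not reproducible; a simple $(sin-dx)/dx$ form is plausible too,
   and the two agree to first order in the asymmetry.
5. **Cortical index.** The percentage of brain-mask voxels at or above 45%
   of the active report's reference ("at least" — the threshold itself
   counts). The complementary surface QC metric, `low_value_fraction`, is
   the percentage of sample points *strictly below* 45%; values there
   indicate possible false delineation. Which reference the thresholds use
   is not fixed by the method description; we apply the active
   normalization of the current report and flag this as an interpretation.

## The lobe atlas and normal database

Landmarks are assigned to 12 regions (cerebellum dx/sin, frontal med/dx/sin,
temporal dx/sin and medial dx/sin, parietal dx/sin, occipital; reports add
total cerebellum) by sampling single-lobe phantoms at each landmark — the
region with maximal intensity wins, ties break toward the lower region
index. The left-hemisphere labelling is then mirrored to the right across
the mid-sagittal plane (nearest reflected landmark), so the atlas is exactly
symmetric; median regions straddle the midline and are left unpaired. A
machine-readable override (landmark index to region) replaces interactive
adjustment. The normal database stores per-point and per-region means and
SDs ($n-1$), separately per normalization, plus the cortical-index mean/SD;
`zscore_patient` returns $(x - \mu)/\sigma$ with SD-zero points flagged
rather than divided.

## The digital phantom

The generator stands in for both the training examinations and the
Monte-Carlo lobe phantoms of the original workflow. It emulates:

* a brain-shaped closed surface: a cerebral ellipsoid (semi-axes
  65 x 82 x 60 mm; AP length 170 mm) fused with an overlapping cerebellar
  ellipsoid bulging posterior-inferiorly;
* a cortical uptake shell (12 mm) around a lower-uptake white-matter
  interior (40% of cortex) and a zero-uptake ventricular ellipsoid;
* partial-volume boundaries (one-voxel linear occupancy ramp), a Gaussian
  PSF of 10 mm FWHM matching reconstructed SPECT resolution, and Poisson
  counting noise applied to the blurred image (blur before noise, emission
  statistics) — `counts_scale = 1` puts about 100 counts in a cortical
  voxel, i.e. shell SNR near 10;
* ground truth: the analytic surface landmarks, brain/ventricle masks,
  per-voxel lobe labels and the applied rotation.

Training populations are sampled with six anatomy-like degrees of freedom
(per-axis cerebral scales, SD 5%; cerebellar scale, SD 10%; sagittal vault
bend, SD 0.12; AP taper, SD 0.06), balanced so that the five retained modes
all carry substantive variance — mirroring the modelling intent that the
retained modes describe real anatomical variation, not numerical residue.

What the phantom does **not** emulate: gyral/sulcal texture, scatter and
attenuation physics, camera-orbit effects, asymmetric pathology, or real
anatomical covariance between structures. Passing phantom tests therefore
demonstrates the correctness and internal consistency of the algorithms —
not clinical accuracy on patient data, which would require a real normal
cohort.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere a volume is sampled at points; samples
  outside the grid read 0 and projection rays leaving the volume warn.
* Rasterization from a landmark surface uses per-ring radius functions on a
  canonical angular grid with pole extrapolation from the cosine ring
  spacing; the cortical shell is bounded by the surface eroded radially (in
  3D) by the cortex thickness, giving lateral end caps.
* Surface normals are angle-weighted vertex normals with virtual pole
  vertices closing the lateral caps (area weighting biases cap normals).
* Degenerate inputs raise typed errors: collinear landmark sets (rank),
  mismatched correspondence counts, empty brain masks, non-positive
  references, regions with no sample points, landmarks unassignable to any
  lobe.
* Determinism: every stochastic component (phantom noise, training
  variation, simulate) is seed-controlled; alignment, model building,
  fitting and quantification are deterministic given their inputs.

## Known limitations

* Mode coefficients of a fitted surface are identifiable only up to the
  boundary-localization bias field of the image operator. At 10 mm PSF the
  steepest-gradient edge has a smooth, geometry-dependent bias of a few
  tenths of a millimetre (largest near the cerebellar crease and the
  lateral poles); its projection onto individual modes can reach several
  times $0.1\sqrt{\lambda_k}$ even when the mean surface error is well
  under half a voxel. Surface-level accuracy is the robust quantity;
  per-mode coefficients should not be over-interpreted.
* The fit assumes one connected, star-shaped-per-slice brain surface; it is
  not designed for severe defects that break the cortical shell.
* The atlas is purely geometric (sector rules on the phantom); on real data
  the original workflow adjusted labels visually, which the override file
  emulates.

## Problem sizes used by the test-suite

Unit tests run the full algorithms on 64-voxel grids at 4 mm spacing (the
same 256 mm field of view as the clinical 128 x 2 mm matrix), with
200-replicate noise checks on 32-voxel grids; the end-to-end
parameter-recovery checks and the acceptance script run at the full
128 x 128 x 128, 2 mm configuration. These sizes were chosen so the whole
suite exercises every code path at full anatomical scale at least once
while staying comfortable to run repeatedly during development.
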