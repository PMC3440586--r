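# asmbrain

Automated quantification of regional cerebral blood flow (rCBF) SPECT
volumes with an active-shape brain model.

Perfusion SPECT with a flow-trapped tracer (e.g. 99mTc-HMPAO) is usually
read visually; quantification is what makes reports reproducible and
comparable across readers and time points — particularly in the dementia
work-up, where the question is often a subtle, regional reduction of
cortical uptake. `asmbrain` implements a fully automated pipeline for users
who need such numbers from reconstructed SPECT volumes: nuclear-medicine
physicists and methods researchers building normal databases and regional
perfusion reports.

## The method

A **point-distribution shape model** encodes brain-shape variability:
training surfaces, each described by L = 546 corresponding landmarks on
closed sagittal curves, are aligned by generalized Procrustes analysis and
decomposed by PCA,

    x  =  x̄ + P b,      |b_k| ≤ 3 √λ_k,

with the K = 5 largest-eigenvalue modes retained. A new scan is analysed in
five steps:

1. **Rotation** — the sagittal orientation is the first principal axis of
   the brain-voxel cloud (plus a site offset); the volume is derotated.
2. **Delineation** — the model is fitted by the active-shape algorithm:
   boundary search along surface normals (intensity interval + steepest
   outward gradient), then a clamped, confidence-weighted model projection,
   iterated to convergence.
3. **Normalization** — voxel counts are scaled so a reference value reads
   100%: cerebellar cortical mean, cerebellar maximum (hottest voxel + 26
   neighbours), or whole-cortex mean; all three are reported.
4. **Cortical projection** — 3010 sample points interpolated from the 546
   landmarks each take the maximal count along their inward normal down to
   9% of the brain length (≈ 15 mm); sample points aggregate into 13
   lobar regions with left-right asymmetry indices
   100·(CBF_sin − CBF_dx) / ((CBF_sin + CBF_dx)/2).
5. **Cortical index** — the percentage of brain voxels at or above 45% of
   the reference, plus a surface QC metric (fraction of sample points
   below 45%, flagging false delineation).

A digital brain phantom (cerebral + cerebellar ellipsoids, cortical shell,
ventricles, PSF blur, Poisson noise, full ground truth) generates training
populations and validation volumes; `build_normal_database()` /
`zscore_patient()` turn a set of normal reports into per-point and
per-region normal values and compare patients against them.

## Worked example

```r
library(asmbrain)

spec  <- phantom_spec(grid_size = 64, voxel_mm = 4)     # 256 mm FOV, PSF 10 mm, Poisson noise
scan  <- generate_brain_phantom(spec)
train <- generate_training_set(29, phantom_spec(grid_size = 64, voxel_mm = 4,
                                                counts_scale = 0), seed = 11)
model <- shape_model(train, n_modes = 5)
model
#> Point-distribution shape model: 546 landmarks, 5 modes, 29 training shapes
#>   retained variance: 97.4%  (scale removed during alignment)

fit <- fit_active_shape(model, scan$volume)
fit
#> Active-shape fit: 546 landmarks, 14 iterations, converged
#>   final mean movement: 0.07536 mm
#>   b = 0.009467, 0.0006479, 0.003457, -0.007515, 0.001352

lobes  <- lapply(setNames(brain_regions(), brain_regions()),
                 function(r) generate_lobe_phantom(spec, r))
atlas  <- assign_lobes(fit$landmarks, lobes)
report <- quantify_scan(scan$volume, fit$landmarks, atlas)
report
#> rCBF quantification: 3010 sample points, brain length 161.8 mm (projection depth 14.6 mm)
#>
#> Regional means (% of reference):
#>                  cerebellum_mean cerebellum_max cortex_mean
#> cerebellum                 100.0          107.4        96.6
#> cerebellum_dx               99.8          107.2        96.4
#> cerebellum_sin             100.2          107.6        96.8
#> frontal_med                103.5          111.2       100.0
#> frontal_dx                 103.3          111.0        99.8
#> frontal_sin                102.8          110.5        99.3
#> temporal_dx                103.8          111.5       100.3
#> temporal_sin               104.4          112.2       100.8
#> temporal_med_dx            105.1          112.9       101.5
#> temporal_med_sin           105.5          113.3       101.9
#> parietal_dx                102.6          110.2        99.1
#> parietal_sin               102.8          110.4        99.3
#> occipital                  103.3          111.0        99.8
#>
#> Asymmetry indices (sin vs dx, %):
#>              cerebellum_mean cerebellum_max cortex_mean
#> cerebellum              0.36           0.36        0.36
#> frontal                -0.49          -0.49       -0.49
#> temporal                0.57           0.57        0.57
#> temporal_med            0.40           0.40        0.40
#> parietal                0.24           0.24        0.24
#>
#> Cortical index (%>= 45%):
#> cerebellum_mean  cerebellum_max     cortex_mean
#>            84.2            90.2            81.9
#> Low-value fraction (%< 45%):
#> cerebellum_mean  cerebellum_max     cortex_mean
#>               0               0               0
```

Reading the numbers: every region sits near 100% of the cerebellar mean —
the phantom is a healthy brain with uniform cortical uptake, so only
noise-level regional structure and sub-percent asymmetries remain. Under
the cerebellar-maximum reference all values drop (the maximum is a higher
reference than the mean would be on a noiseless volume, but Poisson noise
inflates a maximum statistic); the whole-cortex reference recentres the
cortical regions on 100 by construction. The cortical index counts the
white-matter interior and ventricles below 45% of the reference; the zero
low-value fraction says no surface point reads implausibly low counts,
i.e. the delineation is sound.

Real scans enter the same pipeline through `read_volume("scan.nii.gz")`
(and `rotate_volume`/`estimate_rotation` for orientation); fitted surfaces,
models and reports serialize to JSON (`save_shape_model`,
`load_shape_model`).

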