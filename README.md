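# thrombodens

Automated measurement of the **entire-thrombus density distribution** for
acute ischemic stroke CT, in R.

## The problem

The occluding thrombus in large-vessel stroke appears as a filling defect on
CT angiography (CTA) and as material of variable attenuation on non-contrast
CT (NCCT). Its Hounsfield-unit (HU) density reflects clot composition
(RBC-rich clot is denser than fibrin/platelet-rich clot) and is a candidate
marker for thrombolysis response. The standard manual measurement — the mean
of three small spherical ROIs placed inside the thrombus on NCCT — is
observer-dependent and samples a tiny fraction of a heterogeneous object.

`thrombodens` implements the automated alternative: segment the whole
thrombus on CTA (contralateral-artery seeding, mirror-symmetry mapping,
intensity-based region growing), project it onto NCCT by rigid
mutual-information registration, and characterise the **complete voxel
density distribution**:

median, IQR (Q3 − Q1), SD, min/max, skewness *G1*, excess kurtosis *G2*,
volume (mm³), Shapiro–Wilk normality — plus a simulated 3-ROI manual
measurement with a tunable hyperdense-seeking observer-bias model, and the
full agreement toolbox (Bland–Altman limits *mean ± 1.96 SD*, ICC(A,1),
paired *t*, OLS with 95 % CIs, Kruskal–Wallis).

Because no public ground truth exists for this task, the package ships a
synthetic phantom generator: paired CTA/NCCT head phantoms with a
mirror-symmetric arterial tree, an occluding thrombus with a known mixture
density distribution, partial-volume blur, CT noise, and a known rigid
misalignment. Every pipeline stage is validated against phantom truth.

## Worked example

```r
library(thrombodens)

# a phantom pair with known truth (96^3 voxels, 0.5 mm isotropic)
ph <- generate_phantom(phantom_spec(seed = 3))

# the full automated measurement
rec <- run_case(ph$cta, ph$ncct, ph$truth$seeds)
print(rec$density_summary)
#> entire-thrombus density: n = 1334 voxels, volume 166.8 mm^3
#>   mean 42.7, median 44.6, SD 7.8 HU; range [29.8, 56.1]
#>   IQR 12.6 HU (Q1 35.0, Q3 47.5); skewness 0.05, excess kurtosis -1.33
#>   Shapiro-Wilk p = 2.09e-15 (normal: FALSE)

ph$truth$density_summary$median   # ground truth
#> [1] 45.56525

# simulated manual 3-ROI measurement with hyperdense-seeking observers
mm <- simulate_manual(ph$ncct, ph$truth$thrombus_ncct,
                      observer_policy(beta = 0.8, seed = 1))
print(mm)
#> manual_measurement [observer]: ROI means 54.0, 52.0, 51.6 HU -> overall 52.6 HU
```

The measured median (44.6 HU) sits within 1 HU of the phantom's ground
truth (45.6 HU). The manual value (52.6 HU) overshoots the entire-thrombus
median:
the observer model seeks locally hyperdense material, reproducing the
overestimation that motivates whole-thrombus measurement. Over a phantom
cohort, `bias_curve()` shows the overshoot shrinking as true density rises
(negative correlation), i.e. manual measurement compresses the separation of
low- and high-density thrombi.

Real volumes are read and written with `read_volume()` / `write_volume()`
(NIfTI-1 `.nii`/`.nii.gz` and MetaImage `.mha`/`.mhd`), transforms with
`read_transform()` / `write_transform()` (plain text). A command-line
interface with the same stages lives at
`system.file("cli", "thrombodens.R", package = "thrombodens")`
(subcommands: `generate`, `segment-vessel`, `map-symmetry`,
`segment-thrombus`, `register`, `measure`, `simulate-observers`, `agree`,
`replicate`, `run-case`, `run-cohort`).

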