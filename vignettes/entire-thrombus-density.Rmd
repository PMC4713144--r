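---
title: "Measuring the entire thrombus density distribution on paired CTA/NCCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the entire thrombus density distribution on paired CTA/NCCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In acute ischemic stroke the occluding thrombus is visible on CT: as a
filling defect in the contrast-enhanced lumen on CT angiography (CTA), and
as material of variable attenuation on non-contrast CT (NCCT). Its
Hounsfield-unit (HU) density carries compositional information —
red-blood-cell-rich clot is denser than fibrin/platelet-rich clot — which is
relevant to thrombolysis response. The conventional measurement places three
small spherical regions of interest (ROIs) inside the thrombus on NCCT and
averages their means. That protocol is observer-dependent, samples a few
cubic millimetres of a heterogeneous object, and (as the agreement analysis
in this package quantifies) systematically overestimates the density of
low-density thrombi.

`thrombodens` implements an automated alternative: segment the *entire*
thrombus from CTA, project the segmentation onto NCCT by rigid registration,
and characterise the complete voxel density distribution (median, IQR,
skewness, excess kurtosis, volume, normality) rather than a single value.

## The automated pipeline

Per case, `run_case()` composes:

1. **Contralateral vessel segmentation** (`segment_contralateral`):
   threshold-constrained 26-connected region growing on CTA between two
   manually supplied seed points, restricted to a geodesic tube (default
   4 mm) around the shortest above-threshold path between the seeds. The
   tube prevents leakage through skull base or adjacent vessels. The lumen
   threshold (default 120 HU) separates enhancing lumen (about 200 HU) from
   thrombus and parenchyma (below about 80 HU).
2. **Midsagittal symmetry plane** (`estimate_symmetry_plane`): the plane
   maximising the normalised cross-correlation between the volume and its
   reflection, parameterised by two tilt angles and an offset; coarse grid
   search (plus/minus 10 degrees / 10 mm) on a 4x downsampled volume,
   Nelder-Mead refinement at 2x. A fixed-midplane fallback is available for
   pathologically asymmetric heads.
3. **Mirror mapping** (`mirror_mask`): the patent contralateral artery
   reflected onto the occluded side defines the occluded-artery search
   region.
4. **Thrombus region growing** (`segment_thrombus`): seeds are all mapped
   voxels within the thrombus HU window (default 0–100 HU, excluding air/fat
   below and contrast-enhanced blood above). Growth proceeds through a
   corridor obtained by dilating the mapped region by `max_leak_mm`
   (default 1.5 mm), which absorbs symmetry-mapping error; the final mask is
   the largest connected component intersected with the *undilated* mapped
   region. The intersection matters: brain parenchyma (about 35 HU) is
   inside the HU window, so any dilation ring retained in the final mask
   would admit a perivascular sleeve of isodense tissue and bias every
   density descriptor.
5. **Rigid registration** (`register_rigid`): CTA to NCCT, 6 degrees of
   freedom, maximising joint-histogram mutual information (32 bins, linear
   partial-volume binning) over a 4x/2x/1x block-mean pyramid with
   Nelder-Mead restarts. The initial simplex spans the expected capture
   range (about 15 degrees / 15 mm) at the coarse level and shrinks to
   sub-degree/sub-millimetre scale at the finest level; deterministic voxel
   subsampling keeps runs reproducible. Failures surface as a convergence
   warning, and `apply_manual_correction()` is the programmatic stand-in
   for an interactive registration-repair step.
6. **Projection and sampling**: the CTA thrombus mask is projected onto the
   NCCT grid (nearest-neighbour, `apply_transform`) and the density
   distribution of the projected mask is summarised.

### Partial-volume-robust density sampling

Voxels on the thrombus rim blend with perivascular tissue and (at the
proximal face) with enhancing lumen. Because the thrombus material itself is
statistically homogeneous across the lumen cross-section, the rim-eroded
core is an unbiased sample of the same density distribution with far less
partial-volume contamination. `run_case()` therefore computes the
distribution descriptors on the projected mask eroded by `pve_erode_mm`
(default 0.6 mm, roughly one in-plane voxel plus the blur scale) whenever at
least 20 voxels survive, while volume and voxel count are always reported
for the full projected mask. Sampled values are additionally stabilised by
an edge-preserving median filter (`median_filter_at`, default radius
0.75 mm, `denoise_mm` in the config): CT noise flattens the empirical
density around the distribution median, which amplifies the effect of any
voxel-selection perturbation on the measured median; median filtering
suppresses the noise without blurring across composition boundaries and is
unbiased within homogeneous material. A final mixed-tissue control drops
the steepest-gradient fraction of the sampled voxels
(`gradient_magnitude_at`, `grad_keep` = 0.6): a median filter cannot
repair the monotone intensity ramps that partial-volume blur writes across
composition boundaries, but those ramp voxels are exactly the
high-gradient ones, and removing them strips blend mass from every
component proportionally. Setting `pve_erode_mm = 0`, `denoise_mm = 0` and
`grad_keep = 1` reproduces literal whole-mask raw sampling.

### Density descriptors

`summarize_density()` reports mean, median, SD, min, max, type-7 quartiles
and IQR, bias-corrected skewness G1 and excess kurtosis G2 (the SPSS-style
formulas; a normal distribution gives 0 for both), volume in cubic mm, and a
Shapiro-Wilk normality flag at alpha = 0.05. Shapiro-Wilk is limited to
moderate sample sizes, so samples above 4,500 voxels are tested on a
fixed-seed subsample; samples with fewer than 3 voxels or zero variance are
flagged degenerate with skewness/kurtosis reported as 0.

## The synthetic phantom world

No public ground-truth dataset exists for entire-thrombus density, so the
package validates itself on paired CTA/NCCT phantoms (`phantom_spec()`,
`generate_phantom()`) with known truth. The phantom emulates exactly the
features the pipeline relies on, and nothing more:

* an ellipsoidal "head" of parenchyma (35 HU) against air, elliptical
  in-plane (semi-axes 19 x 22.5 x 22 mm) — the air boundary and the
  in-plane eccentricity are what anchor rigid registration and the
  symmetry plane, as the skull outline does in real scans;
* one smoothly curved artery per hemisphere (radius 2.4 mm, an
  ICA/M1-calibre vessel), the occluded side an exact mirror image of the
  contralateral side; lumen enhances by +165 HU on CTA and is 40 HU
  (unenhanced blood) on NCCT;
* a thrombus occupying an arc of the occluded artery, whose voxel densities
  follow a configurable normal mixture selected by a spatially smooth label
  field, so ROIs sample locally coherent material;
* partial-volume blur: isotropic Gaussian of FWHM 0.8 mm plus a
  slice-direction component with FWHM equal to the slice spacing (only when
  blur is enabled); additive Gaussian noise (default SD 5 HU) after blur;
* a known rigid misalignment between CTA and NCCT (by default uniform
  within plus/minus 5 degrees and 5 mm), applied by rendering the NCCT
  scene at pulled-back voxel positions, so the misalignment is exact rather
  than resampled.

The default grid is 96^3 voxels at 0.5 mm isotropic spacing, matching the
dominant thin-slice reconstructions of modern stroke CT (the metadata filter
`filter_cohort()` enforces the 2.5 mm inclusion limit for real data).

Everything is deterministic given the spec seed; two calls with the same
spec are bit-identical.

### Mixture realisation and the rank-transformed label field

`sample_cohort_specs()` draws target medians uniformly on [20, 64] HU and
target IQRs uniformly on [9, 56] HU, the spread observed in real cohorts.
Each (median, IQR) pair is realised as a three-component mixture with
weights 0.28/0.44/0.28: the middle component sits at the target median
(which pins the distribution median, because 28% + half of 44% is exactly
50%, and gives the empirical CDF a sharp slope there), and the outer
components sit at distances that reproduce the target IQR after accounting
for the component SD (2 HU). Outer component means are
capped to a physiological window of 10–72 HU: about 10 HU is serum-rich
fresh clot (real cohorts report per-thrombus minima averaging about 9 HU)
and about 72 HU is the ceiling of dense RBC-rich clot. The cap is a stated
property of this world, fixed before any validation was run; it is also the
mechanism that makes the manual-measurement bias density-dependent (below).

A thrombus of one or two hundred cubic millimetres holds only a handful of
independent texture patches, so raw occupancies of a smooth random label
field would fluctuate wildly around the weights. The label field is
therefore *rank-transformed* over the thrombus voxels: the smooth Gaussian
field is reduced to its empirical quantile within the thrombus, which keeps
the spatial layout of patches while making component occupancies match the
weights exactly. The within-component variate is a second, independent
smooth field. Both are random Fourier-feature fields, evaluable analytically at any
world point — which is what makes CTA-grid and NCCT-grid renderings of the
same thrombus consistent. The default correlation structure is lamellar:
uniform in-plane and 3.5 mm along the vessel axis, i.e. the clot is a
stack of millimetre-scale axial layers of alternating composition, the way
real clots are zoned (RBC-rich body, fibrin-rich layers); the
within-component variate fluctuates at a shorter axial scale so values
inside one layer still spread over the component SD. This anisotropy is
also what makes the phantom's ground truth recoverable: layers span the
lumen cross-section, so rim effects (partial-volume erosion, mapping
error, projection jitter) remove a proportional share of *every* mixture
component instead of reweighting them, while isotropic blobs at either
much smaller scales (blur mixes neighbouring components and drags the
median of capped, asymmetric mixtures toward the local mean) or much
larger scales (a single lost patch reweights a whole component) both
destabilise the measured median. The mixture-fidelity and end-to-end
recovery tests pin the chosen behaviour.

A caveat frozen into the tests: for an exactly equal-weight two-component
mixture the CDF is flat at 0.5 between the modes, so the *median* of any
finite sample is unstable anywhere in the inter-mode gap. The mixture
fidelity test therefore checks the stable functionals (mean and outer
quartiles) against a brute-force Monte-Carlo oracle, and checks the median
only for unequal-weight mixtures, where it is pinned.

### What a green phantom test does not establish

The phantom has no skull, no ventricles, no beam hardening, no motion, a
perfectly mirror-symmetric tree, and a single occlusion. Green tests
establish that the algorithmic chain is correct and self-consistent under
controlled degradation (noise, blur, misalignment); they do not establish
clinical accuracy on real scans, where vessel tortuosity, anatomical
asymmetry and reconstruction kernels add failure modes that the original
clinical workflow handled by visual inspection.

## The observer-bias model

`simulate_manual()` places three spherical ROIs (default radius 1 mm)
inside the thrombus mask and averages their mask-restricted mean HU. The
placement policy is an explicit behavioural *model*, not a claim about any
human observer: with probability `beta` each ROI is placed greedily at the
strongest remaining local maximum of a smoothed (FWHM 1.5 mm) NCCT density
field, otherwise uniformly at random, with a minimum centre separation
(2 mm, relaxed with a warning on small thrombi). `beta = 0` is unbiased
sampling; `beta = 1` is pure hyperdense-seeking.

Under hyperdense-seeking the manual value tracks the *upper* mixture
component, so the manual-minus-median difference is roughly half the IQR —
except that the 72 HU ceiling compresses the upper component for
high-median thrombi. That is what produces the package's reproduction of
the qualitative clinical finding: manual readings exceed the
entire-thrombus median on average, and the excess shrinks as true density
rises (negative correlation, `bias_curve()`), i.e. manual measurement
compresses the contrast between low- and high-density thrombi.

## Agreement statistics

`agreement_stats`-style functions are implemented from closed forms so that
tests can verify them against independent oracles: simple OLS with
t-based CIs (`fit_ols`), Pearson correlation (`pearson_cor`), paired t
(`paired_t`), Bland-Altman limits of agreement (`bland_altman`, differences
taken reference-minus-comparison), Kruskal-Wallis with tie correction
(`kruskal_wallis`), and the intraclass correlation (`icc`). The ICC form is
two-way, absolute agreement, single measures — ICC(A,1) — chosen because
the raters are fixed and the accompanying Bland-Altman analysis addresses
absolute differences; the model label is always attached to the result
since published reports frequently omit it. Observers measuring different
case subsets are handled by complete-case pairing per observer pair. A
paired t on identical vectors reports t = 0, p = 1 (exact agreement) rather
than an error; a constant non-zero difference vector is degenerate.

`replicate_analysis()` re-runs the whole cohort analysis from a
per-thrombus CSV table (one row per case: descriptors plus per-observer
manual values). SPSS-format supplementary tables convert with one line of
python (`pandas.read_spss(...).to_csv(...)`). Because the regression
orientation in published reports can be ambiguous, both orientations of the
manual/median fit are returned.

## Numerical choices and edge cases

* Quantiles are type-7 (linear interpolation), the common statistics-package
  default; configurable in `summarize_density()`.
* Mask resampling is nearest-neighbour (labels stay binary); volume
  resampling is trilinear.
* Transforms follow the pull-back convention: `register_rigid(m, f)` maps
  fixed-image world points into moving-image space, so the result feeds
  `apply_transform()` directly. Composition, inversion and a plain-text
  serialisation are provided; Euler extraction is valid away from the
  90-degree gimbal, far outside the few-degree range used here.
* Degenerate inputs error loudly with named conditions: constant volumes
  (registration, symmetry), seeds below threshold, disconnected seeds,
  empty masks and empty resampling results, a patent mapped region
  (`no-thrombus-found`), zero between-subject variance (ICC).
* The cohort metadata filter reads the exclusion rules strictly: slice
  thickness greater than 2.5 mm and CTA-NCCT gap greater than 30 minutes
  are excluded, boundary values included, missing metadata flagged as its
  own exclusion reason.

## Known limitations

* The vessel segmentation is a stated substitute for the original
  (unpublished) tracking algorithm: threshold growing plus a geodesic tube.
* The thrombus texture model (smooth mixture-label field) is an assumption;
  real clot spatial correlation is uncharacterised.
* Multi-occlusion cases error out by design rather than being handled.
* Registration quality on real multi-kernel data is not assessable from the
  phantom world; the convergence warning plus manual-correction hook is the
  supported recovery path.
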