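---
title: "Predicting MCI-to-AD conversion from structural MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MCI-to-AD conversion from structural MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Some patients with mild cognitive impairment (MCI) progress to Alzheimer's
disease within a few years ("converters"); others remain stable. Structural
MRI carries early signatures of conversion — focal grey-matter (GM) loss in
the hippocampus, thalamus, precuneus, and posterior cingulate among others —
and two families of deep-learning classifiers exploit them: a *whole-volume*
3D CNN that reads the entire normalized scan, and a *region-guided* CNN that
reads only small patches centered on coordinates where a group-level
statistical analysis found significant GM differences, together with the
Z-scores of those coordinates.

`mciprog` implements the entire workflow — synthetic data generation,
preprocessing, voxel-based morphometry (VBM), coordinate-guided patch
extraction, both classifiers, and evaluation — as a self-contained, fully
seeded R package. Real patient data is deliberately out of scope; every
stage is exercised end-to-end on simulated cohorts whose ground truth is
known, so each claim the package makes is testable.

## The synthetic data model

`make_template()` builds a deterministic head phantom on the canonical
template grid (default 113 x 137 x 113 voxels at 1.5 mm; the affine maps
0-based voxel indices to MNI-style millimeters with the x axis flipped,
field of view x in [-84, 84], y in [-120, 84], z in [-72, 96]). The head is
an ellipsoid with a white-matter core, a GM shell, a thin CSF rim,
ventricle-like CSF pockets, and three deep-GM nuclei (thalamus-,
hippocampus-, and posterior-cingulate-like) at the default atrophy
coordinates (24, -30, 0), (-15, -37.5, 3), (3, -60, 24). Planting lesions
on locally symmetric GM structures keeps the true statistical peak at the
planted coordinate; a lesion planted on the cortical shell's radial
gradient would have its peak displaced by the product of effect and
anatomy, making "the peak recovers the center" ill-posed.

A cohort (`generate_cohort()`) assigns each subject a group (progressive /
stable), an age drawn uniformly from 60–85 years, a sex bit, and one or two
scans (second scan with probability 0.5). Progressive subjects lose GM
multiplicatively at each lesion center: `gm * (1 - f * exp(-d^2 / (2 r^2)))`
with peak fraction `f` (default 0.4) and spatial scale `r = 8` mm; both
groups age-scale GM by 0.002 per year around age 72.5. A raw scan
(`synthesize_scan()`) renders tissue intensities (CSF 0.25, GM 0.55, WM
0.85 against a 0.01 background), moves them through a random rigid+scale
transform (translations up to 4 mm, rotations up to 3 degrees, scale within
2%), multiplies a random order-3 polynomial bias field (log-sd 0.1 over the
head — the amplitude is defined over the head region, where it matters, not
over the empty grid corners), and adds Gaussian noise (sd 0.02). The
planted transform, bias field, and noise level are attached as ground
truth.

What the generator does *not* emulate: real cortical folding, tissue
texture, pathology heterogeneity, scanner-specific artifacts, or nonlinear
anatomical variability between subjects (all subjects share one template
anatomy). Passing tests therefore demonstrate the *mechanics* of the
pipeline — recovery of planted signals under the stated corruption model —
not clinical performance on real data.

## Preprocessing

1. **Bias-field correction** (`correct_bias()`). The field is modeled as
   `exp(P(x))` with `P` a polynomial of order 3 in normalized grid
   coordinates, estimated by least squares in the log domain. A plain fit
   of log-intensity absorbs the head's own tissue contrast, so voxels are
   first classified into three tissue classes by a Gaussian mixture fit on
   a locally-normalized image (intensity divided by its ~25 mm in-mask
   mean, which cancels any smooth field before classification); only
   confidently classified voxels in twice-eroded class interiors enter a
   joint regression of log-intensity on per-class intercepts plus the
   polynomial, with two robust reweighting passes that drop outliers such
   as focal lesions. On a pure-tissue phantom this recovers planted fields
   nearly exactly (correlation > 0.99); on head-like volumes with
   partial-volume gradients recovery is partial, because within-class
   intensity structure is genuine anatomy that no polynomial decomposition
   can fully separate from bias. When the input has fewer than three
   intensity modes the method falls back to the plain log-polynomial fit,
   which is exact for constant-tissue phantoms. The field is normalized so
   the mean in-mask intensity is preserved. The regression is identified
   only when the selected pure voxels span at least two tissue classes; on
   very coarse grids (voxels of 4 mm and above) partial volume can leave no
   pure interiors, in which case the scan is deliberately left uncorrected —
   a bounded residual field is far less harmful downstream than a
   field estimate contaminated by anatomy.
2. **Tissue segmentation** (`segment_tissues()`): a prior-free
   three-component Gaussian mixture (unequal variances, fit with `mclust`
   on a deterministic subsample), components labeled CSF < GM < WM by
   ascending mean; posteriors are evaluated in closed form at every masked
   voxel and sum to one.
3. **Spatial normalization** (`normalize_to_template()`): a 9-parameter
   transform (translation, rotation, anisotropic scale about the head
   center) maximizing normalized cross-correlation with the template
   intensity, by coordinate descent with step halving over a 3-level image
   pyramid (downsampling factors 4, 2, 1; up to 60,000 in-mask sample
   points per level; steps halve until below 0.01 voxel / 0.01 degree).
   Typical recovery of planted misalignment is within ~0.5 mm / 0.5
   degrees. The same transform is then applied to the GM posterior map
   (trilinear interpolation throughout).
4. **Smoothing** (`smooth_volume()`): separable Gaussian with
   `sigma = FWHM / (2 sqrt(2 ln 2))` converted to voxels per axis
   (FWHM 8 mm by default), replicate-padded so constant volumes are
   preserved exactly.
5. **Quality control**: `qc_correlation()` computes the pairwise Pearson
   correlation of preprocessed scans over the brain mask and flags pairs
   below 0.8 (the conventional acceptance band for co-registered
   anatomy); `qc_slice_montage()` writes a deterministic slice montage.

## Group-level analysis (VBM)

One design row per subject (multi-scan subjects contribute the voxelwise
mean of their smoothed GM maps), columns `[intercept, group, age(centered),
sex]`, group coded progressive = 1. The default contrast is
stable - progressive, so converters' GM loss appears as positive
statistics. Ordinary least squares runs vectorized over all mask voxels
(`beta = (X'X)^{-1} X'y`, `sigma^2 = RSS/(n-p)`), the contrast t map is
converted to Z-scores through the exact t CDF in log space (no saturation
for |t| up to hundreds), and the familywise error rate is controlled by
permutation: the group labels are permuted (covariates fixed), the maximum
|Z| over the mask is recorded per permutation, and the threshold is the
order statistic corresponding to the `1 - alpha` quantile of the reference
set including the observed arrangement. Simple relabeling is exact here
because the synthetic null is fully exchangeable; with real covariate
structure a Freedman–Lane scheme would be preferable, a documented
limitation. Null calibration on pure-noise cohorts (100 replicates,
12 subjects/group, 8^3-voxel masks, 200 permutations) gives an empirical
familywise error of about 0.05–0.06 at alpha = 0.05.

Peaks are 26-neighborhood local maxima above threshold (ties broken toward
the lowest linear voxel index), greedily retained in descending Z subject
to a minimum pairwise world distance (default 8 mm), and reported in MNI
millimeters — the familiar VBM results-table schema (Z-score, peak x/y/z,
free-text anatomical label).

One numerical subtlety: when effects are strong, the classical t map is
nearly flat over the lesion ("plateau"), and its spatial argmax is driven
by per-voxel variance-estimate noise rather than by the effect profile.
`contrast_tmap(..., var_smooth_fwhm_mm = 8)` therefore offers SnPM-style
variance smoothing (a pseudo-t) for localization; FWE thresholds are always
computed from the classical statistic. With variance smoothing, planted
lesions at effect fraction 0.4 and 20 subjects/group are localized to
within 3 mm (2 voxels at 1.5 mm) for all three centers in ~90% of seeds.

## The two classifiers

All network code (3D cross-correlation with per-filter bias, leaky ReLU,
2x2x2 max pooling, dense layers, inverted dropout, Adam, and the explicit
backward passes) is implemented in the package against its own C++ kernels
and verified against numerical differentiation; determinism is part of the
training contract.

* **Whole-volume model**: three (conv 3x3x3, leaky ReLU slope 0.01, pool)
  blocks with 32/64/128 filters (valid padding — the usual framework
  default; the architecture's padding is otherwise unstated), flatten,
  dense 128, dropout, sigmoid output.
* **Region-guided model**: a shared per-patch encoder — conv 32 (same
  padding), pool, conv 64 (same), pool (patch side 15 -> 7 -> 3), flatten
  (3^3 x 64 = 1728), dense 128 — applied identically to each of the K
  patches; the K embeddings are concatenated with the K peak Z-scores
  (width 128K + K = 2838 at K = 22), then dense 128, dropout 0.5, sigmoid.
  The per-patch dense-128 embedding is what pins the printed 2816/2838
  widths; the flatten width follows from the shapes.

Training minimizes binary cross-entropy (predictions clipped at 1e-7) with
minibatch Adam (batch size 2), records per-epoch train/validation loss and
accuracy, and returns the best-validation-loss parameters. `saliency_map()`
backpropagates the output logit to the input and reports the absolute
gradient.

## Experiment orchestration and desk-scale choices

`run_experiment()` chains simulation, preprocessing, QC, group analysis,
patch extraction, training, and evaluation. Subjects are split 80:10:10 at
the subject level, stratified by group (train = floor(0.8 n), test =
floor(0.1 n), validation = the remainder); all scans of a subject share one
subset, and the absence of subject overlap is asserted, not assumed. The
group analysis runs on training subjects only, so peak coordinates never
see validation or test data — reusing all subjects would leak labels
through the coordinate choice.

The default experiment runs at deliberately reduced size so that a complete
run takes minutes on one CPU: 20 subjects per group on a (39, 47, 39) grid
at 4.5 mm (the same field of view as the full template, and the coarsest
grid on which three valid-conv/pool blocks retain usable spatial
structure), effect fraction 0.5, reduced network widths (whole-volume
4/8/16 filters + dense 32; region encoder 8/16 + dense 32 + fusion 32),
learning rate 1e-3, 15 epochs, and no dropout — at these widths and sample
sizes dropout's multiplicative noise is larger than the class signal and
prevents convergence, whereas the full-size architectures trained on
hundreds of scans are where the 0.5 rate belongs (and it remains the
model-spec default). The paper-scale training defaults (5 epochs, batch 2,
learning rate 1e-4) remain the defaults of `train_config()`.

Under these conditions both classifiers reliably reach perfect test
accuracy on strongly separated cohorts, so the expected ordering (region
at least as accurate as whole-volume when atrophy is confined to the peak
coordinates) holds as a tie.

## Numerical and convention choices

* Voxel coordinates are 0-based everywhere in the public API (the NIfTI
  convention); conversion to R's 1-based subscripts happens only at
  indexing. MNI-to-voxel conversion rounds half away from zero.
* FWHM-to-sigma uses `2 sqrt(2 ln 2)` exactly; interpolation is trilinear;
  patch edges are zero-padded; volumes are treated as RAS-consistent with
  the declared affine.
* All randomness flows from one integer seed through named substreams
  (cohort, per-scan corruption, permutations, splitting, initialization,
  training), so every pipeline stage is independently reproducible.
* Degenerate inputs have declared conventions: constant volumes scale to
  all zeros; zero-variance voxels get t = 0; an empty peak table is legal
  (but the region model refuses to build on one).

## Problem sizes used by the test suite

Unit tests run on small phantoms (block phantoms around 40^3, coarse 3 mm
templates). The deeper suites use: QC reproduction — 6 scans through the
full chain at 3 mm; FWE calibration — 100 null replicates of 12
subjects/group on 8^3 masks with 200 permutations; coordinate recovery — 5
seeds of 20 subjects/group at the full 1.5 mm resolution; learning — 3
seeds of 20 subjects/group at 4.5 mm. The acceptance script preprocesses 8
subjects at the full 1.5 mm resolution. These sizes are the package's
validation conditions; they were chosen to make each property measurable
in minutes on a single CPU.

## Known limitations

* The synthetic anatomy is a single template: registration never faces
  true inter-subject variability, and segmentation never faces real
  partial-volume mixtures of folded cortex.
* Bias-field recovery on heads is partial (see above); only pure-tissue
  phantoms support near-exact recovery.
* Permutation uses simple relabeling, not Freedman–Lane.
* GM maps are used unmodulated (no Jacobian scaling of the warped
  posteriors), so the analysis detects concentration differences rather
  than absolute volume differences.
* No nonlinear registration; the 9-parameter affine is adequate only
  because the simulated misalignment is itself rigid+scale.
* Headline clinical accuracies from real cohort studies are not
  reproducible from synthetic data and are not claimed; the package
  validates mechanics, calibration, and architecture, not clinical effect
  sizes.
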