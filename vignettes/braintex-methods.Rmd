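---
title: "Methods: GLCM texture, volumetry and group statistics in braintex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GLCM texture, volumetry and group statistics in braintex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

braintex implements the image-analysis and statistics pipeline used in
volumetric texture studies of neurodegeneration: per-ROI three-dimensional
grey-level co-occurrence (GLCM) texture features and total-brain-volume
(TBV) normalized volumetry on labeled T1-weighted volumes, compared across
three diagnostic strata (neurodegeneration-negative cognitively normal,
N-CN; neurodegeneration-positive cognitively normal, N+CN;
neurodegeneration-positive mild cognitive impairment, N+MCI) with ANCOVA,
Bonferroni post hoc tests and partial eta squared. Because clinical MRI of
this kind is rarely shareable, the package ships a synthetic labeled-brain
phantom generator with the same statistical structure, so the entire
pipeline is testable end to end.

## The texture chain

For each ROI the chain is, in order:

1. **Partial-volume trimming.** Voxels with intensity outside
   $[\mu - 3\sigma,\ \mu + 3\sigma]$ are excluded, where $\mu$ and $\sigma$
   are the mean and *population* standard deviation (divide by $n$) of the
   ROI's own voxels. Bounds are inclusive so the $\sigma = 0$ case is
   well defined (everything retained). By Chebyshev's inequality at least
   8/9 of voxels always survive. Trimming statistics are per ROI by
   default — the trimming is part of the per-ROI normalization chain — with
   precomputed (e.g. whole-brain) statistics available through the
   `trim_stats` argument of `quantize_roi()`.
2. **CSF normalization.** Intensities are divided by the subject's mean
   lateral-ventricle CSF signal, removing global scanner/gain scale.
3. **Re-quantization to 32 grey levels.** Equal-width binning over the
   retained voxels' min–max range:
   $\mathrm{level}(v) = \min(L, \lfloor (v - v_{\min})/(v_{\max} - v_{\min})
   \cdot L\rfloor + 1)$, $L = 32$ by default. The binning range is not
   dictated by the source description of the method; per-ROI min–max
   (the fixed-bin-number convention dominant in radiomics) is used because
   it preserves within-ROI contrast structure and makes the chain invariant
   to any positive affine intensity transform. Degenerate ranges map to
   level 1. Levels are 1-based (1..32) to match the feature formulas'
   index range.
4. **Co-occurrence counting.** Symmetric GLCMs at distance 1 over the 13
   canonical directions (one per antipodal pair of the 26-neighborhood;
   symmetric accumulation of each ordered pair is what makes 13 rather than
   26 directions sufficient). Both pair members must be retained ROI
   voxels; there is no padding and no wraparound.
5. **Averaging.** The 13 normalized matrices are averaged elementwise and
   renormalized to sum 1. Normalizing per direction *before* averaging
   weights directions equally even though their pair counts differ at mask
   boundaries. Directions with zero valid pairs are excluded from the
   average, not entered as zero matrices; an ROI where no direction yields
   a pair produces a flagged record, never a silent zero.
6. **Features.** Haralick contrast $\sum_{i,j}(i-j)^2 P_{ij}$ (bounded by
   $(N-1)^2 = 961$ at $N = 32$), entropy $-\sum P_{ij}\ln P_{ij}$ in nats
   (natural log, stated explicitly because the supplementary formula of the
   source analysis is not printed), and autocorrelation
   $\sum_{i,j} i\,j\,P_{ij}$.

A GLCM is declared normalized when $|\sum P - 1| \le 10^{-6}$; feature
functions reject anything else.

## Volumetry

Volumes are voxel counts times voxel volume (cc). The narrative phrase
"sum of voxel intensities" sometimes used for ROI volumetry conflicts with
cc units; count-based volumetry is the default and an intensity-sum mode is
available (`roi_volume_cc(mode = "intensity_sum")`). TBV is the sum of all
segmented structures including ventricular CSF, mirroring the
whole-segmentation definition. Lobe rows aggregate volumes by exact
addition; lobe textures run the full chain once on the merged (union) mask,
so trimming and quantization happen at the lobe granularity — a per-ROI
feature-averaging mode exists as an alternative
(`lobe_aggregate(mode = "texture_roi_mean")`).

## Group statistics

Each ROI is analysed with ANCOVA: `y ~ group + age + sex + education + V`,
where `V` is TBV for volume analyses and the ROI's own volume for texture
analyses. The group effect is the partial (Type III) F from the
full-versus-reduced comparison; with a single factor plus covariates Types
II and III coincide (asserted in the tests against `car::Anova`). Sex is
dummy-coded; covariates are not standardized (irrelevant to F, keeps
adjusted means interpretable). Partial eta squared is
$F\,\mathrm{df}_1 / (F\,\mathrm{df}_1 + \mathrm{df}_2)$.

Post hoc comparisons are pairwise contrasts of covariate-adjusted group
means (predictions at the covariate means) using the model's pooled error
variance — the estimated-marginal-means convention, cross-checked against
`emmeans` in the tests — with Bonferroni correction
$p_{\mathrm{adj}} = \min(1, 3p)$. Whether the original analyses compared
raw or adjusted means is not stated; adjusted means are the default here.
Pattern strings follow the compact table notation: groups with no
significant pair are omitted, mutually non-different groups are joined by
commas, ordered clusters by `<`/`>` written so the earliest group label
comes first (`"a, b > c"`, `"a < b < c"`, `"a < c"`); the pattern is empty
when the omnibus p is at or above 0.05. No correction is applied across
ROIs (mirroring the within-ROI-only convention); a global FDR can be
layered on the long-format stats table if desired.

Demographics use one-way ANOVA (continuous) and Pearson chi-square without
continuity correction (categorical). Inter-rater agreement uses the
two-way random-effects, absolute-agreement, single-measure intraclass
correlation ICC(2,1) — the standard choice for two exchangeable raters
rating the same subjects; the form is not named in the source description,
so it is stated here and computed from the two-way ANOVA mean squares with
the F-based 95% CI.

## The phantom generator

`generate_label_volume()` places each ROI as a cuboid of (approximately,
after cuboid rounding; the realized count is stored back) its nominal voxel
count on a non-overlapping grid. Cuboids rather than anatomical shapes:
the analysis operates on per-ROI masks, and exact voxel accounting enables
volume tests at one-voxel resolution.

`generate_intensity_volume()` builds each ROI as

$$ I = \text{base mean} + \text{anatomy field} + \text{texture field} + \varepsilon $$

* the **anatomy field** is a broad Gaussian random field (default SD 20
  intensity units, FWHM 6 voxels), identical in construction across
  groups. It represents the smooth within-ROI intensity structure real
  parcellations have, and it is load-bearing: per-ROI min–max quantization
  removes one global scale, so with a *single* fluctuation field the
  contrast of the quantized ROI would not increase with the field's
  amplitude (for an unsmoothed field the two effects cancel exactly, and
  for a smoothed field contrast actually falls as the field grows relative
  to the iid noise floor). Anchoring the quantization range with a fixed
  broad component makes the fine-scale texture dial map monotonically onto
  GLCM contrast, which is the property the group effects rely on (verified
  by paired-seed tests).
* the **texture field** is the group dial: a Gaussian random field smoothed
  to FWHM 2 voxels and rescaled to SD `texture_sigma` (default 15) times
  the group's per-ROI multiplier.
* $\varepsilon$ is iid noise (default SD 5).

Both random fields are mean-centred and rescaled to their exact target SD
over the ROI, so ROI means are exact and the dials are interpretable.
The CSF reference region (base mean 100 versus grey-matter means of
275–320) carries no texture.

Atrophy is boundary erosion: `apply_atrophy()` removes
$\mathrm{round}(f \cdot n)$ voxels by iterative 6-connected erosion, peeling
the final partial shell in a fixed lexicographic sweep. The sweep order is
deterministic by construction (a random peel order can isolate cuboid
corner voxels and break 6-connectivity); it lands within one voxel of the
target and keeps the ROI connected. Every subject in every group receives
a baseline erosion fraction (mean 0.05, SD 0.02, truncated at 0) as
individual anatomical variability — without it volumes would be
group-deterministic and the volume ANCOVA would have no residual variance.
Group-level atrophy adds on top; the reference group's effect object is
identically zero.

Covariates: age and education are truncated normal draws (age $\ge 60$,
education $\ge 0$), sex is Bernoulli in the group's female proportion, and
MMSE (clamped to 0–30) is generated for demographics-table realism but
never used by the pipeline statistics. The default cohort recipe
(`default_cohort_spec()`) uses group sizes 183/111/155 and the published
reference cohort's covariate distributions (see
`reference_cohort_stats()`); its group effects encode the
texture-before-volume progression: temporal texture multipliers 1.3 (N+CN)
and 1.6 (N+MCI), atrophy confined to hippocampus/entorhinal at N+CN and
spread across temporal ROIs at N+MCI.

## Simulation studies and their problem sizes

Two simulation suites exercise the statistics end to end, both on a
reduced phantom (two grey-matter ROIs of $8^3$ voxels plus CSF, 20
subjects per group) chosen so hundreds of cohorts run in minutes while
each ANCOVA still has realistic n:

* **Null calibration:** 500 cohorts with no injected effects; the per-ROI
  ANCOVA omnibus must reject within the 95% binomial interval around
  $\alpha = 0.05$ and post hoc patterns must be empty except at the
  false-positive rate. A separate 500-replicate direct simulation of the
  volumetric null checks the uniformity of the p-distribution
  (Kolmogorov–Smirnov at the 1% level).
* **Dissociation recovery:** effect phantoms inject an entorhinal texture
  effect at both N+ stages (multipliers 2.0 and 2.6) and atrophy (fraction
  0.08, subject jitter SD 0.03) only at the N+MCI stage. The pipeline must
  report the qualitative signature — texture significant in both N+ groups,
  volume significant only in N+MCI — in at least 80% of replicates. The
  effect magnitudes are free parameters of the phantom (no quantitative
  pathology-to-texture mapping exists to copy) and were sized for
  comfortable power at n = 20 per group. They are deliberately not larger:
  extreme atrophy makes regional volume nearly collinear with the group
  factor, and the volume covariate then absorbs the texture effect — an
  intrinsic property of texture ANCOVAs that adjust for regional volume,
  worth remembering when interpreting real data.

## What the phantom does and does not show

Passing tests on the phantom demonstrate that the chain computes what it
claims (oracle-equivalent co-occurrence counting, exact volume accounting),
that its invariances hold (scale invariance of the normalization chain,
inversion invariance of contrast/entropy, mask locality), and that the
statistics are calibrated and powered under the generator's assumptions.
They do not certify behavior on real MRI: the phantom has cuboid ROIs,
Gaussian stationary texture, no bias fields, no Rician noise, no motion,
no partial-volume mixing beyond what trimming emulates, and unilateral
ROIs (no hemisphere pooling). Results on clinical data additionally depend
on segmentation quality, which is upstream of this package (it consumes
preprocessed intensity + label volumes).

## Numerical conventions

* Population SD (divide by $n$) everywhere in the trimming statistics.
* Inclusive trim bounds; $\sigma = 0$ retains everything.
* Degenerate quantization range maps all voxels to level 1.
* Empty co-occurrence directions are excluded from averages; an all-empty
  ROI is flagged (`flagged = TRUE`, NA features).
* GLCM normalization tolerance $10^{-6}$ on input validation; averaged
  matrices renormalized to sum 1 exactly.
* Erosion targets `round(f * n)`; realized counts within $\pm 1$ voxel.
* All randomness flows from a single seed per cohort; identical specs give
  bit-identical cohorts, features and tables.
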