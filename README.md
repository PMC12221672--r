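# braintex

3D grey-level co-occurrence (GLCM) texture and volumetric analysis of
labeled brain MRI, with the group statistics used in neurodegeneration
imaging studies, and a synthetic labeled-brain phantom generator that makes
the whole pipeline testable without clinical data.

## Who this is for

Neuroimaging researchers comparing regional brain *texture* (microstructural
heterogeneity) and *volume* across diagnostic groups — e.g. SNAP cohorts
stratified into neurodegeneration-negative cognitively normal (N-CN),
neurodegeneration-positive cognitively normal (N+CN), and
neurodegeneration-positive MCI (N+MCI). Texture changes tend to appear
earlier and more widely than volume loss; this package computes both
measures through the same reproducible chain and tests them with the same
models.

The pipeline consumes preprocessed data: a T1-like intensity volume plus an
integer ROI label volume per subject (NIfTI), and a subject table with
group, age, sex and education. Parcellation, bias correction and skull
stripping are upstream and out of scope.

## The method

Per ROI, the texture chain is:

1. partial-volume trimming to [μ − 3σ, μ + 3σ] (population SD, inclusive);
2. intensity normalization by the subject's mean lateral-ventricle CSF
   signal;
3. re-quantization to N = 32 grey levels (per-ROI min–max binning);
4. symmetric co-occurrence matrices at voxel distance d = 1 over the 13
   unique 3D directions, averaged after per-direction normalization;
5. Haralick features on the averaged matrix P:

   - contrast  Σᵢⱼ (i − j)² P᙮ᵢⱼ
   - entropy   −Σᵢⱼ Pᵢⱼ ln Pᵢⱼ
   - autocorrelation  Σᵢⱼ i·j·Pᵢⱼ

Volumes are voxel counts in cc, with total brain volume (TBV) as the sum of
all segmented structures. Group comparisons use ANCOVA
(`y ~ group + age + sex + education + TBV` for volumes, regional volume in
place of TBV for textures), partial (Type III) F for the group effect,
partial eta squared `η²ₚ = F·df₁ / (F·df₁ + df₂)`, and Bonferroni-corrected
(p < 0.05/3) pairwise post hoc tests on covariate-adjusted means, reported
as compact patterns such as `a > b > c` or `a, b > c`. Demographics use
one-way ANOVA and chi-square; inter-rater agreement uses ICC(2,1) with an
F-based 95% CI.

The phantom module generates labeled cohorts with controllable fine-scale
texture heterogeneity (a smoothed random field per ROI) and boundary-erosion
atrophy, with covariates drawn from published reference-cohort
distributions (`reference_cohort_stats()`), so power and type-I behavior of
the full pipeline can be measured by simulation. See the methods vignette
(`vignettes/braintex-methods.Rmd`) for the model, parameter defaults and
design choices.

## Worked example

```r
library(braintex)

res <- run_full(seed = 42)   # demo-scale phantom: n = 20/20/20, 5% voxel scale
t2 <- res$analysis$table2_volume
t3 <- res$analysis$table3_texture
```

Selected volume rows (mean (SD) in cc per group; F, p, η²ₚ, post hoc):

```
            roi          N-CN          N+CN         N+MCI        F         p partial_eta_sq   posthoc
  temporal_lobe 5.499 (0.037) 5.488 (0.029) 5.288 (0.057)  82.0392 5.929e-17        0.75585  a, b > c
    hippocampus 0.325 (0.009) 0.310 (0.007) 0.288 (0.005) 105.4083 3.379e-19        0.79910 a > b > c
     entorhinal 0.171 (0.003) 0.165 (0.003) 0.152 (0.005)  76.1366 2.609e-16        0.74181 a > b > c
      precuneus 0.768 (0.018) 0.763 (0.017) 0.765 (0.019)   0.6151 5.444e-01        0.02268
```

and the temporal-lobe texture row (merged-mask GLCM contrast):

```
            roi       N-CN       N+CN      N+MCI      F         p partial_eta_sq  posthoc
  temporal_lobe 15.2 (0.6) 16.5 (0.8) 17.6 (0.8) 16.844 2.175e-06        0.38861 a < b, c
```

Reading it: the phantom injects temporal atrophy only at the N+MCI stage
but raises temporal texture heterogeneity at both N+ stages, and the
pipeline recovers exactly that dissociation — hippocampal/entorhinal volume
falls stepwise (`a > b > c`), parietal volume shows nothing, and
temporal-lobe contrast is already elevated in the still-cognitively-normal
N+ group (`a < b, c`). Effect sizes are large because the demo phantom is
small and clean; they are illustrations of the machinery, not clinical
estimates.

Single components work standalone:

```r
partial_eta_squared(50.755, 2, 442)
#> [1] 0.1867675

# two ordinal raters agreeing on most of 30 subjects
set.seed(1)
a <- round(runif(30, 0, 4))
b <- pmin(4, pmax(0, a + rbinom(30, 1, 0.2) - rbinom(30, 1, 0.2)))
unlist(icc_two_rater(a, b))           # two-way random effects, absolute agreement
#>       icc    ci_low   ci_high   flagged
#> 0.9147686 0.8298178 0.9584003 0.0000000
```

A thin CLI over the same functions ships in `inst/scripts/braintex`
(subcommands `simulate`, `extract`, `analyze`, `full`).

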