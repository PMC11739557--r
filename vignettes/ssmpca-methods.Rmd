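---
title: "Metabolic covariance pattern analysis with ssmpca: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance pattern analysis with ssmpca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmpca)
```

## The model

The scaled subprofile model (SSM) treats a cohort of spatially normalized
FDG-PET volumes as multiplicative compositions of a group mean profile, a
subject global scaling factor, and a small number of shared spatial
covariance sources. Writing $P_{sv}$ for the intensity of subject $s$ at
masked voxel $v$,

$$\log P_{sv} = \mu_v + g_s + \sum_k a_{sk}\,\phi_{kv} + \varepsilon_{sv},$$

where $g_s$ is the (uninteresting) global scale, $\phi_k$ are spatial
patterns shared across subjects, and $a_{sk}$ are subject loadings. The
pipeline inverts this model step by step:

1. **Masking.** Each scan is thresholded at a fraction (default 0.35) of its
   own whole-volume maximum, which retains mainly gray matter; the per-scan
   masks are intersected across the derivation cohort so every subject has
   signal at every retained voxel. The intersection is what makes the
   subsequent log transform well defined everywhere (no $\log 0$).
2. **Log transform** turns the multiplicative global factor into an additive
   row constant.
3. **Double centering.** Removing each subject's mean across voxels
   eliminates $g_s$ *exactly*; removing the voxel-wise control mean
   afterwards expresses every subject as a residual profile relative to the
   reference group. The control-mean vector is retained with the pattern
   (its `reference_offset`), so a prospective scan is processed identically
   to a derivation scan.
4. **PCA in voxel space**, computed through the subjects-by-subjects
   covariance matrix (numerically identical to a dense SVD, and cheap when
   voxels far outnumber subjects). Components are unit-norm, mutually
   orthogonal, and oriented so the patient group's mean score is at least
   the control group's: PCA signs are arbitrary, and disease patterns are
   conventionally reported with elevated patient expression.
5. **Component selection**: the shortest prefix of components whose
   cumulative variance fraction reaches the target (default 50%).
6. **Logistic combination**: an exhaustive search over subsets of the
   candidate components (up to 4 by default) for the logistic model of group
   membership with minimum AIC; the selected components are combined with
   their fitted slopes and rescaled to unit norm. The rescaling factor is
   recorded; it only multiplies raw scores by a constant, which the
   z-transformation absorbs.

A subject's **pattern expression** is the projection of their
row-centered, reference-offset log profile onto the pattern weights. It is
computable one scan at a time — no other scan enters the calculation — so
prospective scoring of new cohorts equals batch scoring, and derivation
subjects rescored prospectively reproduce their derivation scores exactly.
Scores are z-transformed against the control group (mean 0, SD 1, $n-1$
denominator).

## Guarding the subset search against separation

AIC compares maximized likelihoods, and the logistic likelihood has no
maximum under complete separation: the deviance of a separated fit tends to
0 and its AIC to $2(k+1)$, less than any honestly fitted model. With a
strong disease component the groups are *nearly* separated along it, and
almost any noise component can finish the job in-sample, so an unguarded
exhaustive AIC search systematically returns disease-plus-noise mixtures
whose ridge-refit coefficients give the noise components weight parity with
the disease component. On simulated cohorts with a 3-SD loading shift this
degraded ground-truth recovery from $|r| \approx 0.93$ (disease component
alone) to $0.6$–$0.7$; penalized-likelihood variants of the criterion do
not repair it, because a separated fit genuinely is a perfect in-sample
fit.

`fit_logistic_combination()` therefore screens candidates for a marginal
group difference in their subject scores (Welch t-test, $p < 0.05$) before
the subset search; if nothing passes, the single most associated component
is kept. The AIC search, the subset cap, and the ridge refit for separated
winners (fixed penalty $10^{-3}$, slopes only — relevant only to
coefficient values, since a single-component pattern is invariant to its
coefficient after unit-norm rescaling) all operate unchanged downstream of
the screen. At weak, realistic effect sizes the screen rarely removes a
truly contributing component, and multi-component, non-contiguous
selections remain reachable. Setting `screen_p = 1` disables the guard.

## Bootstrap validation

`bootstrap_pattern()` assesses which voxel weights are stable under
resampling: subjects are redrawn with replacement *within* each group
(preserving the two-group design the logistic step needs), the entire
derivation is rerun on each resample — double centering recomputed, PCA,
prefix selection, logistic combination restricted to the point estimate's
subset size — and each resampled pattern is sign-aligned to the point
estimate (flipped when their correlation is negative). Per-voxel percentile
intervals (default 95%, 1000 iterations) are formed from the aligned
weights, and voxels whose interval contains zero are zeroed. Design
choices, each of which the literature leaves open:

- **Stratified (within-group) resampling**, not pooled: a pooled resample
  can produce unusable group imbalances.
- **Percentile intervals**, not BCa: matches the plain reading of "95%
  confidence interval" at 1000 draws without bias-correction machinery.
- **Subset handling** per iteration is a switch: `fixed_size` (default)
  reruns the search at the point estimate's subset size, `frozen` reuses
  the point estimate's component indices, `full` reruns the open search.
- Degenerate resamples (a group collapsing to one distinct subject, or
  rank-0 residuals) are redrawn, with a capped retry budget.

Surviving voxels are always a subset of the pattern's support; raising the
confidence level never increases the surviving count; and a fixed seed
reproduces the result bit for bit.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the pipeline inverts:
an ellipsoidal template with a high-intensity gray-matter-like shell
(intensities above 35% of the volume maximum, so the standard mask retains
the shell and drops interior and background), $K$ smooth orthonormal
components built by smoothing white noise on the shell and Gram-Schmidt
orthogonalization, Gaussian subject loadings with the patient mean of
component 1 shifted by `effect_size` loading-SDs, uniform per-subject
global scales, smooth additive log-space noise, and clinical covariates
linearly coupled to the component-1 loading with noise.

Defaults mirror the reference study design and are fixed once:

| parameter | default | rationale |
|---|---|---|
| grid, voxels | $32^3$, 2 mm | smallest grid that holds a shell phantom with a few thousand mask voxels |
| group sizes | 18 HC + 16 patients + 8 validation | the study's cohort sizes |
| components $K$ | 3 | "small number of shared sources" |
| `effect_size` | 3 | separation strength producing the study-like clear group difference |
| `loading_sd` | 1 | loading scale is arbitrary; 1 fixes the unit |
| `noise_sd` | 0.05 | ~5% voxel-level metabolic noise in log space |
| global scale | $U(0.8, 1.2)$ | ±20% injected-dose/uptake variation |
| covariate coupling | slope −8, noise SD 14 | gives $|r| \approx 0.5$ between tremor score and loading, the magnitude of reported clinical correlations; the negative sign mirrors the reported inverse severity correlation |

What the generator does *not* emulate: PET resolution and Poisson count
noise, partial-volume effects, anatomical variability, registration error,
scanner differences. Passing recovery tests therefore demonstrates that the
pipeline correctly inverts its own generative model at realistic sizes and
noise — not that it is robust to everything real data contains.

## Numerical choices

- Smoothing is separable Gaussian convolution with
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel units,
  half-sample-reflect boundaries, kernels normalized so constant volumes
  are exactly invariant; kernels narrower than $10^{-3}$ voxels are treated
  as identity.
- Voxel order within a mask is ascending linear index in column-major
  storage, fixed per mask, making every vectorized quantity deterministic.
- Eigenvalues below $10^{-10}$ of the largest are treated as rank
  deficiency; centering contracts are asserted at $10^{-10}$; the PCA/SVD
  oracle equivalence holds to $10^{-8}$ after sign alignment.
- Ties in the variance-prefix rule cannot occur away from exact equality;
  the prefix comparison uses a $10^{-12}$ slack so a fraction exactly at
  the target is included.
- `z_transform()` refuses reference groups with zero score variance;
  `build_profiles()` refuses non-positive masked intensities, naming the
  subject and voxel.

## Separation, bias, and how the tests measure it

Two biases documented in the study design are reproduced faithfully rather
than corrected. First, in-sample separation is optimistic: the derivation
explicitly selects the components that best discriminate the derivation
groups, so even at zero true effect the derived pattern separates its own
cohort by construction. Second, when no independent control cohort exists,
validation subjects are z-scored against the derivation controls, whose
reference mean is biased low under the derived pattern. Consequently the
test suite checks the growth of separation with effect size on
*prospectively scored validation cohorts*, averaged over four fixed seeds
(single-cohort estimates at small effects are dominated by these biases
plus sampling noise), and treats in-sample separation only as a positivity
check.

## Problem sizes in the test suite

Unit and invariant tests run on $16^3$ cohorts of 8+8 subjects (about 800
mask voxels), chosen as the smallest sizes at which every pipeline stage is
non-degenerate. Recovery checks run the full study design — $32^3$ grids,
18+16 subjects, 20 seeds — and complete in seconds per cohort. Bootstrap
oracle checks use 50 iterations; the 1000-iteration operating point is a
default of the user-facing functions, not rerun in the tests.

## Known limitations

- The analysis mask derives from intensity thresholds, not from an
  anatomical atlas; at very low thresholds it can include non-brain signal.
- The voxel-weight correlation p-value ignores spatial autocorrelation and
  is anti-conservative; it is returned with an explicit warning flag.
- Spatial normalization/registration is out of scope: all inputs are
  assumed pre-aligned to a common space, and alignment is verified only by
  shape/affine comparison.
- Patterns are linear; metabolic changes that express nonlinearly in log
  space are folded into the residual noise.
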