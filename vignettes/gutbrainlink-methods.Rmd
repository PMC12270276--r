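---
title: "Methods: a multistage microbiota-gut-brain linkage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multistage microbiota-gut-brain linkage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gutbrainlink` implements, as reusable and tested components, the multistage
analysis chain used to link a genus-level gut microbial abundance (the
motivating application is *Alistipes* in major depressive disorder) to the
fecal metabolome, resting-state brain function, and behavior:

1. untargeted-metabolomics quality control and normalization;
2. a group comparison of microbial abundance (Mann–Whitney U);
3. first-component partial least squares regression (PLSR) linking the
   abundance to the metabolite matrix, with a permutation null and a
   loading-based top-20% metabolite selection;
4. hypergeometric pathway over-representation of the selected sets;
5. five resting-state fMRI metrics (ALFF, fALFF, ReHo, FCD, VMHC) with
   whole-brain-mean standardization and cluster-mean extraction;
6. covariate-adjusted partial Spearman correlation screens with
   Benjamini–Hochberg FDR;
7. regression-based single-mediator analysis with bootstrap percentile
   confidence intervals.

Because no subject-level cohort of this kind is publicly deposited, the
package ships a synthetic-cohort generator (`cohort_config()`,
`simulate_subjects()`, `simulate_metabolite_panel()`,
`simulate_volume4d()`) that plants every effect the pipeline is designed to
detect, with the ground truth attached to each object. All statistical
claims made by the test suite are claims about this stated synthetic world,
not about any real cohort.

# Metabolomics QC

The filter cascade runs in a fixed, logged order on each ion mode
independently:

* **QC/blank ratio** — a metabolite is background if
  mean(QC areas) / mean(blank areas) < 3. The ratio uses replicate *means*
  (the simplest reading of "peak area ratio"); a zero blank mean with
  positive QC signal counts as infinite (kept), and a metabolite with no QC
  signal at all (0/0) is removed as background.
* **RSD** — the coefficient of variation across pooled-QC technical
  replicates, n−1 denominator; strictly greater than 30% is discarded.
* **Presence** — at least 80% of *study samples* (QCs and blanks do not
  count) must be nonzero; the boundary is inclusive.
* **Imputation** — zeros are the missingness code (untargeted peak tables
  distinguish no NA convention); a zero becomes one fifth of its column's
  minimum positive value.
* **Normalization** — each column is divided by its QC-replicate mean,
  passed through the generalized logarithm
  `glog(x) = log2((x + sqrt(x^2 + lambda^2))/2)`, and z-scored.

The boundary conventions (`< 3` removes, `> 30%` removes, `>= 80%` keeps)
follow the stated rules literally and are asserted at the exact boundary in
the tests. Two parameters are genuinely under-determined by the method
description and are therefore explicit, documented interpretations: the
QC-normalization statistic (we use the replicate mean) and the glog
`lambda` (we default to each column's minimum positive normalized value,
which keeps the transform finite at zero and adapts to column scale). A
useful consequence of the QC-mean normalization is exact scale invariance:
multiplying all raw areas of one metabolite by any k > 0 leaves its
z-scored output unchanged, which the suite checks.

# PLSR linkage

With a univariate response, the first PLSR component has a closed form: the
unit vector maximizing cov(Zw, microbe) is the normalized cross-covariance
vector. We compute it directly rather than via iterative NIPALS — the
result is identical, deterministic, and testable against an independent SVD
of the cross-covariance. The sign is fixed so cov(scores, microbe) ≥ 0,
making the overall Pearson correlation non-negative; negating the microbe
vector flips the weights and swaps the selected sets, which is tested as an
invariance.

The permutation test reshuffles the subject labels (default 5000 times),
refits the **full** component per shuffle, and uses the add-one estimator
`p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`, one-sided on the sign-fixed
correlation. The smallest achievable p at 5000 shuffles is 1/5001 ≈ 0.0002,
matching the convention of reporting "P < 0.0002" at that resolution. The
choice of a one-sided test follows from the sign convention: after fixing
cov(scores, microbe) ≥ 0 the observed statistic is non-negative by
construction and a two-sided rule would be redundant.

Selection takes `k = floor(0.20 p)` metabolites of each sign (most-positive
and most-negative contribution loadings, ties broken by identifier so
selection is deterministic). If fewer than `k` loadings carry the required
sign, the set truncates with a warning — the quota interpretation of an
ambiguous "top 20% with positive and negative loadings".

# Resting-state metrics

All five metrics operate on a masked 4-D array with a repetition time, and
every map is zero outside the mask.

* **ALFF** — mean single-sided amplitude-spectrum value over 0.01–0.1 Hz,
  computed on the *unfiltered* series. The amplitude convention is
  `2|FFT_k|/T` (halved at the Nyquist bin) and the DC bin is excluded: a
  constant offset is not a fluctuation. The normalization choice is
  immaterial after mean-1 standardization, which the homogeneity test
  verifies.
* **fALFF** — band amplitude mass over total amplitude mass (all bins above
  DC); lies in [0, 1]; an all-zero series is assigned 0 and flagged.
* **ReHo** — Kendall's coefficient of concordance between a voxel and its
  in-mask 26-neighborhood, classic form without tie correction; isolated
  voxels get 0 and are flagged. Mask-edge voxels use whatever neighbors the
  mask provides (m adapts), rather than padding.
* **FCD** — count of in-mask voxels with Pearson correlation strictly
  greater than 0.25; self excluded; constant series connect to nothing.
* **VMHC** — correlation of each voxel with its reflection across the
  midline of the first array axis; the effective mask is the intersection
  of the mask with its own reflection. True anatomical symmetric
  registration is out of scope; the array grid defines the midline.

ReHo, FCD and VMHC are conventionally computed on band-limited data; the
package provides an FFT-domain band-pass (`bandpass()`) that zeroes all
bins outside 0.01–0.1 Hz including DC. `standardize_map()` rescales to a
within-mask mean of exactly 1; `extract_cluster_means()` reduces a map to
the per-cluster means that feed the correlation and mediation stages.

# Correlation screens and FDR

The partial Spearman coefficient is Pearson correlation between the
covariate-residualized midrank vectors of x and y — the standard
construction when only the method name is given. Categorical covariates
expand to indicator columns; the p-value uses the t reference with
n − k − 2 degrees of freedom. Complete cases only, with exclusion counts
reported. FDR control is Benjamini–Hochberg (the default reading of "the
FDR method"); the family is configurable (`block`, `per_feature`,
`per_target`) because family boundaries are not derivable from the method
description — the default treats each screen call as one family.

# Mediation

The classic product-of-coefficients single-mediator model: three OLS fits
sharing the intercept and nuisance covariates give a (X→M), b and c′
(Y ~ X + M), and c (Y ~ X); the indirect effect is a·b and the identity
c = a·b + c′ holds exactly for OLS with identical covariate sets (asserted
to 1e-8 on every fit). Inference is a percentile bootstrap over subject
rows (default 5000 resamples, 95% interval; BCa is deliberately not the
default because only a "bootstrap CI" is specified and the percentile
interval is the simplest faithful reading). Degenerate resamples are
redrawn with a capped budget. Variables enter in raw units by default;
`standardize = TRUE` z-scores X, M and Y first — reported indirect effects
depend on this choice, which is why it is a visible flag rather than a
hidden convention. A mediator that is an exact linear function of the
treatment makes b unidentifiable; the package raises a rank-deficiency
error rather than returning an arbitrary solution, and the "noiseless
chain" closed-form test therefore gives the mediator an exactly
X-orthogonal component.

Candidates for the mediation screen are chained from the correlation
screens: (x, m, y) qualifies iff x–m and m–y were both flagged at q < 0.05.
No multiplicity correction is applied across triples by default (each
pathway is judged by its own CI), matching the reporting convention of the
emulated analysis.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ k) with universe N, pathway size K and selected-set size n, followed
by BH-FDR across pathways — standard ORA practice when only the annotation
database is named. The default universe is the annotatable metabolites
(intersected with an optional user universe such as the QC survivors); the
background choice is configurable because it is not otherwise determined.

# The synthetic world

`cohort_config()` defaults *are* the stated world: 111 patients and 102
controls (the emulated study's sizes); a 0.8 SD patient shift of log
abundance; 100 metabolites per ion mode with indices 1–10 loading +0.8 and
11–20 loading −0.8 per SD of log abundance; three mediation chains with
a = 0.5, b = 0.4, c′ = 0.1; unit residual SD per layer; covariates (age,
gender, education, site, plus FD for imaging) leaking into every layer
with coefficient 0.1. Where the emulated study states no value (it reports
no usable effect sizes), these were chosen once, before any acceptance
measurement, for adequate detection power at the stated sample sizes
(planted loadings ≈ 0.5 against a null loading SD of ≈ 0.1; mediation path
z-scores ≈ 5), and are not revisited.

Abundance is log-normal with an additive log-scale group shift, closed to
[0, 1] by a strictly monotone logistic map — rank-based statistics are
unaffected by the closure, which is why Mann–Whitney is the correct group
test here. The metabolite panel maps latent signals to positive peak areas,
appends pooled-QC replicates (5% CV) and blanks (ratio 10), injects zeros
that stay above the presence threshold, and appends labeled
deliberately-failing metabolites for each filter, so filter tests are exact
set comparisons. The volume simulator sums supported sinusoids and Gaussian
noise and can enforce exact mirror symmetry.

What the generator does *not* emulate: compositional coupling between taxa,
heavy-tailed or batch-structured metabolite noise, spatial autocorrelation
and physiological artifacts in BOLD, item-level behavioral structure, or
missingness mechanisms beyond injected zeros. A green test therefore
establishes correctness of the statistical machinery on data satisfying the
generator's assumptions — not robustness to everything real cohorts do.

# Numerical choices and degenerate inputs

* Midranks everywhere ties arise (Spearman, Mann–Whitney, ReHo).
* Mann–Whitney uses the tie-corrected variance with a 0.5 continuity
  correction; exact enumeration is available (and the default) for
  n1 + n2 ≤ 12; all-tied input returns z = 0, p = 1.
* Zero-variance inputs error with the offending column named; constant
  metabolite columns get loading 0 and are flagged rather than erroring,
  because a constant column is a data property, not a user mistake.
* All seeds derive deterministically from a single master seed; reruns are
  byte-identical, which the end-to-end test asserts.
* The NIfTI-1 codec in `R/nifti.R` exists because the target environment
  provides no R NIfTI reader; it covers uncompressed 3-D/4-D scalar files
  and is validated against an independent reader in the test suite.

# Known limitations

Single-component PLSR only (by design); no exposure–mediator interaction
or multiple mediators; no voxel-wise inference (group-level cluster masks
are an input, not a product); the BH family default is a convention, not a
derivation; enrichment ignores pathway topology. The pipeline establishes
associations and mediation consistency under the model's assumptions — it
cannot establish directionality.
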