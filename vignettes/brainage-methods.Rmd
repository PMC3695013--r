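---
title: "Brain-age estimation and prognostic evaluation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age estimation and prognostic evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainage)
```

## The model and its assumptions

The estimator assumes that normal aging leaves a smooth, monotone imprint
on gray-matter density that is shared across healthy individuals, so that
a regression trained on healthy subjects alone defines a norm against
which pathology appears as an *age offset*. Three consequences shape the
implementation:

* **Train-only fitting.** Both the principal-component basis and the
  regression weights are estimated exclusively on the healthy training
  stratum and then frozen. Scoring a test subject touches no test
  statistic; this is what makes the BrainAGE score interpretable as a
  deviation from the healthy norm rather than from the test cohort.
* **Sex stratification.** Aging trajectories differ by sex, so a separate
  PCA + RVR pair is fitted per sex and scoring picks the matched pair.
  A single-sex mode exists (`allow_single_sex = TRUE`) for small
  experiments; the production default requires both strata.
* **Linear kernel.** The kernel is a polynomial of degree 1 with an
  explicit bias column. Nonlinear kernels have not been found to improve
  age estimation from smoothed gray-matter maps, and the linear kernel
  keeps the model parameter-free apart from the automatically estimated
  hyperparameters.

### Relevance vector regression

The regression is the sparse Bayesian linear model
$y = \Phi w + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$, with
independent priors $w_i \sim N(0, \alpha_i^{-1})$. With the posterior
$\Sigma = (\sigma^{-2}\Phi^\top\Phi + \mathrm{diag}\,\alpha)^{-1}$,
$\mu = \sigma^{-2}\Sigma\Phi^\top y$, hyperparameters are re-estimated by
the classic fixed-point updates
$\alpha_i \leftarrow \gamma_i/\mu_i^2$ with
$\gamma_i = 1 - \alpha_i\Sigma_{ii}$ and
$\sigma^2 \leftarrow \lVert y - \Phi\mu\rVert^2 / (n - \sum_i\gamma_i)$,
pruning basis functions whose precision diverges. We chose full
re-estimation over the fast sequential variant because every quantity has
a closed form that an independent oracle can recompute (the tests do
exactly that), and with cohorts of a few hundred subjects the $n \times n$
kernel is cheap.

**Optimizer constants** (`rvr_config()`): pruning threshold
$\alpha > 10^{12}$; initial $\alpha = 10^{-6}$; initial
$\sigma^2 = 0.1\,\mathrm{var}(y)$; convergence when
$\max_i |\Delta \log \alpha_i| < 10^{-3}$; at most 1000 iterations.
Non-convergence returns the last state with a flagged status and a
warning, never silently.

**Numerical choices.** The posterior is solved through a QR factorization
of the square-root augmented system
$[\Phi/\sigma;\ \mathrm{diag}\sqrt{\alpha}]$, whose conditioning is the
square root of the normal-equation formulation — essential on noiseless
data, where $\sigma^2$ collapses to its floor
($10^{-12}\max(\mathrm{var}\,y, \overline{y^2}, 1)$) and the naive
precision matrix becomes numerically singular. A jittered Cholesky of the
precision is kept as a fallback for rank-deficient augmented systems.
The effective dofs $\gamma_i$ are clamped to $[10^{-12}, 1]$ against
floating-point excursions.

**Sparsity and the polynomial kernel.** A degree-1 kernel design has rank
at most (feature dimension + 1), so its columns are strongly collinear.
On such designs the symmetric fixed point often retains many basis
columns whose precisions are large but finite: sparsity is expressed in
the $\alpha$ magnitudes (the effective dof $\sum\gamma_i$ is small) rather
than by aggressive pruning, and pruning, when it happens, is log-linear
and slow. This is a property of the update scheme, not a defect: on
better-conditioned designs the same code prunes to a handful of relevance
vectors (one of the tests shows 50 noisy observations reduced to 2).
The relevance-vector count reported by the package counts surviving
*training examples*; the bias column is tracked separately.

### Preprocessing

Smoothing uses a separable Gaussian with per-axis standard deviation
$\mathrm{FWHM} / (\mathrm{spacing} \cdot \sqrt{8\ln 2})$ voxels,
implemented as banded convolution matrices. Boundaries are zero-padded
with the truncated kernel renormalized per output voxel: constants pass
through unchanged everywhere, and interior columns still sum to one, so
mass is conserved for gray matter supported away from the grid edge — the
physically relevant case, since segmented maps are zero outside the head.
Downsampling to the coarse analysis grid (default 8 mm isotropic) is a
block average over each coarse voxel's footprint: deterministic,
mass-preserving, and free of new extrema; how the original framework
interpolated to 8 mm is not documented, so this is our choice. The
analysis mask keeps voxels whose mean training gray-matter density
exceeds 0.1 — permissive on purpose, dropping only empty background;
setting the threshold to 0 reproduces whole-image behavior. Voxel
ordering in feature vectors is the array storage order (first axis
fastest), fixed and identical across subjects. Values outside $[0,1]$
are flagged on read and never clipped.

### PCA

All components up to the numerical rank are retained by default: no
variance cutoff is documented for the original framework, and retaining
the rank keeps the kernel regression information-equivalent to the raw
features while shrinking the dimension to at most $n-1$. Features are
not standardized before PCA (an option exists, off by default). Each
component's sign is fixed so its largest-magnitude loading is positive,
which makes serialized models reproducible across linear-algebra
backends.

## The prognostic evaluation layer

* **Operating point.** Tables of accuracy/sensitivity/specificity are
  reported at the max-accuracy point of the ROC, with ties broken toward
  higher specificity. Published analyses of this kind state only that *a*
  threshold was used; max accuracy is the one choice that reproduces the
  published BrainAGE post-test numbers, and it is the package default
  (`select_threshold()`).
* **Confidence intervals** are Wald normal approximations with
  class-specific denominators (all subjects for accuracy, positives for
  sensitivity, negatives for specificity). The Wald form at the pooled
  *n* reproduces published accuracy intervals exactly; whether published
  sensitivity intervals used class-specific or pooled denominators is
  ambiguous, and we document the class-specific choice.
* **McNemar** defaults to the uncorrected $\chi^2=(b-c)^2/(b+c)$ with a
  continuity-correction flag; zero discordance returns an explicit
  "no discordance" outcome instead of a statistic.
* **AUC comparison** uses the paired DeLong covariance with a one-tailed
  alternative, the natural test when a new marker is compared against
  established ones.
* **Cox regression** goes through `survival::coxph` with Breslow ties,
  adjusted for age, education years and sex. Quartile analyses use
  treatment contrasts against the lowest quartile; quartile boundaries
  are interpolated empirical percentiles (type 7), with left-closed
  assignment so boundary scores fall upward. Stable subjects are censored
  at 3 years (1095 days); Kaplan–Meier output includes $1-S(t)$ and the
  $\log(-\log S)$ transform for proportional-hazards checking.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the framework
assumes, not neuroanatomy. A head-like baseline template (smooth logistic
falloff of density 0.85 inside an ellipsoid) loses gray matter linearly
with *effective age* (chronological age + offset $\delta$) on a
contiguous cluster covering 20% of the head support, with slopes of
0.002–0.004 density/year and a ±10% multiplicative sex effect; smoothed
Gaussian noise (SD 0.04, FWHM 6 mm) plays the role of residual anatomy.
The decline is anchored at age 50, the start of the training range.

Sample sizes and ranges mirror the study conditions the framework was
originally evaluated under: 320 healthy training subjects (107 male, 213
female; ages 51–94), 64 held-out healthy subjects, and three MCI
components of 60 subjects (ages 55–88) with mean offsets
$\delta = 0.75 / 5.62 / 8.73$ years and between-subject SD 1.5 years.
Conversion times are exponential with hazard
$\lambda_0 e^{\beta\delta}$, $\beta = \ln 1.10$ (10% greater risk per
offset year) and $\lambda_0 = 7\times10^{-4}$/day, chosen so that ~68% of
the MCI sample converts within 3 years and ~30% within the first year —
the printed cohort fractions; censoring is administrative at 1095 days.
All randomness flows from one master seed through per-subject substreams,
so volumes are bit-reproducible.

**Group labels.** Clinical labels (`sMCI`, `pMCI_late`, `pMCI_early`)
are derived from the *realized* conversion time, exactly as MCI cohorts
are labelled in practice (conversion within 12 months → early; within the
censoring horizon → late; censored → stable). The originally assigned
mixture component and the true offsets live in a separately named truth
table so pipeline code cannot consume them accidentally. This is the one
place where two desiderata genuinely conflict: a pure proportional-hazards
link with $\beta = \ln 1.10$ is unbiased for Cox recovery and makes times
independent of $\delta$ when $\beta = 0$, but label selection then mixes
the components, so realized clinical groups separate less than the
configured offsets do (realized-label AUC for stable vs early converters
is ~0.7, while the assigned components separate at AUC ~0.99; the two
bracket the published 0.83 regime, which no hazard this weak can
reproduce on realized labels). Recovery analyses therefore group by the
assigned component; the realized labels drive the clinical-statistics
demonstrations.

**What passing tests do and do not show.** The generator's decline is
exactly linear and its noise stationary and Gaussian; real cohorts add
nonlinear atrophy, site and scanner effects, segmentation error and
white-matter lesions misclassified as gray matter, none of which are
simulated. Passing recovery tests therefore validates the *machinery*
(feature extraction, train-only reduction, regression, scoring and the
statistics), not the clinical effect sizes.

## Problem sizes

The default experiment (320 + 64 + 180 subjects on a 32×40×32 grid at
4 mm, analyzed at 8 mm) trains and scores in well under a minute on one
core; the replicate Cox-coverage study (50 seeds) runs table-only
simulations and takes a few seconds. Tests use a 16×20×16 grid for the
pipeline round-trips and the default grid for the recovery checks.

## Known limitations

* Brain-age estimates regress toward the training mean; the classic
  age-bias correction is deliberately **not** applied (the evaluated
  framework does not apply it), and is exposed only as the documented
  attenuation of per-year hazard rates estimated from noisy scores.
* The polynomial-kernel design limits RVR pruning (see above); memory use
  is therefore $O(n^2)$ in the training stratum, irrelevant at cohort
  scale.
* Diagnostic-performance CIs are Wald approximations and degrade near
  proportions of 0 or 1; the package flags degenerate 2×2 tables rather
  than switching interval types.
* Upstream segmentation, bias correction and spatial normalization are
  out of scope: inputs are assumed to be registered, segmented
  gray-matter probability maps on a common grid.
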