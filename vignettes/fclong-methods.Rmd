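---
title: "Methods: longitudinal FC change over network blocks"
author: "fclong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal FC change over network blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fclong)
```

## The analysis

fclong implements a longitudinal resting-state functional-connectivity (FC)
analysis built around a sphere-based parcellation of the brain into 264
regions of interest (ROIs) grouped into 14 functional networks. The
pipeline has four stages.

**FC construction.** BOLD signal is averaged within each ROI's 5 mm sphere,
bandpass filtered to 0.01–0.15 Hz (the conventional resting-state band,
which removes scanner drift, heartbeat and most respiratory signal), and
pairwise Pearson-correlated to give a symmetric, unit-diagonal ROI-by-ROI
FC matrix. Raw correlations are kept throughout — no Fisher z-transform —
because every downstream quantity (block means near 0.39, changes near
+0.03, dispersions near 0.26) is defined and reported on the correlation
scale. The strict upper triangle is vectorized in row-major order,
giving 34,716 edge features for 264 ROIs; this ordering is written into
every output header.

**Network-block reduction.** A *block* is the set of edges whose endpoints
lie in a given pair of networks (within-network blocks use all internal
edges). With 14 networks there are 105 blocks; each block's unweighted
edge mean is one "inter-network connectivity". Per-subject longitudinal
change is the older-scan block mean minus the younger-scan block mean.

**Inference.** Each block's per-subject changes get a two-sided one-sample
t-test against zero; p-values are Bonferroni-multiplied by the number of
blocks actually tested (105 for the full atlas) and capped at 1. Two
dispersion summaries are reported side by side because they answer
different questions: `sd_subject`, the standard deviation across subjects
of the per-subject *block-average* change, is what the t-test uses;
`sd_edge_mean`, the mean over the block's edges of each edge's
across-subject change standard deviation, is what an edge-level dispersion
map averages to and is the ~0.26-scale quantity for the headline block.
Relative (percent) change is ambiguous — change over the younger mean,
over the older mean, and the mean of per-subject percentages all differ —
so the summary reports all three rather than guessing.

**Scan-order prediction.** For each subject the two scans' FC difference
is taken with a randomized sign (which scan is subtracted is random), the
sign is the label, and an L2-regularized logistic classifier (inverse
regularization strength C = 1) is trained to recover it. Learning curves
use 20 repetitions per training size; each repetition draws a random
training subset and tests on all remaining subjects. "Bootstrap" here
means repeated random disjoint splits, not resampling with replacement:
evaluation on "the rest" requires the test set to be disjoint from
training (resampling is still available via `scheme = "resample"`).
Blocks are ranked by single-feature accuracy at the largest configured
training size, the asymptotic regime of the curve.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| passband | 0.01–0.15 | Hz | conventional resting-state band |
| TR | 0.735 | s | acquisition sampling interval |
| sphere radius | 5 | mm | parcellation definition |
| C | 1 | — | near-optimal over a broad range of training sizes |
| repetitions | 20 | — | standard for the learning-curve experiment |
| Bonferroni m | blocks tested | — | family-wise control over the block family |
| age groups | <55, >65 | years | "young"/"old" subgroup definitions; 55–65 stays in whole-cohort statistics only |

## The synthetic cohort generator

Real longitudinal imaging cohorts of this kind are access-restricted, so
the package ships a generator whose defaults *are* the study conditions
the analysis targets:

* younger-scan somatomotor–visual (block 0–6) mean 0.39, within-network
  baseline 0.30 and between-network baseline 0.10 (plausible resting-state
  magnitudes; only the 0–6 value is calibrated to a published figure);
* longitudinal shift +0.03 on block 0–6 only;
* marginal per-edge change standard deviation 0.26;
* per-subject block-effect standard deviation 0.11 — not a published
  number but a calibration inference: together with the edge noise it
  puts the positive-change fraction near 60%, the observed regime, and
  it matches the reported ~0.11–0.13 dispersion of per-subject block
  averages, which also motivates the 0.11 subject-baseline offset;
* cross-sectional age effects of 0.031/0.045/0.042/−0.014 (male) on the
  SMT-VIS / SMT-DMN / DMN-VIS / VIS-VIS blocks with 0.035 elsewhere, and
  the corresponding female calibration;
* 2,722 longitudinal subjects; 5,000 per cross-sectional group; sex and
  age-group proportions matching the cohort being emulated.

The per-edge change noise is *derived* as
`sqrt(change_sd^2 - block_effect_sd^2)` so that the marginal per-edge
change standard deviation — the quantity an edge-level dispersion map
measures — equals the configured 0.26 exactly, rather than
`sqrt(0.26^2 + 0.11^2)`.

**Bounds and PSD.** The younger scan is clipped into [−1, 1] (with the
default dispersions clipping there is a >4σ event, so it is essentially
inactive). The older scan is left unclipped by default: with a mean of
0.42 and a change spread of 0.26, a Gaussian model necessarily puts
roughly 1–3% of edge mass above 1, and hard clipping would bias the
recovered mean downward by ~0.002–0.005 and shrink the dispersion —
enough to defeat the generator's purpose of hitting its calibration
targets exactly in expectation. Consumers that need valid correlation
matrices can set `bounded = TRUE` (clip) and/or `psd_repair = TRUE`
(eigenvalue clipping at zero plus diagonal renormalization). Note that
real correlation matrices are automatically bounded and positive
semidefinite; the unbounded default trades that realism for exact
calibration, which is the right trade for parameter-recovery testing.

**Two generator levels.** The FC-level generator above scales to
thousands of subjects in seconds. A timeseries-level generator exists to
exercise extraction and filtering end-to-end: each network gets a
band-limited latent signal, factors are mixed to carry the configured
inter-network correlations (`a_k = sqrt(B_kk)`,
`C_kl = B_kl / (a_k a_l)`, realizable only when that matrix is a valid
correlation matrix — the generator errors otherwise, naming the offending
block), and each ROI is its network factor plus independent band-limited
noise. Noise is band-limited so that the pipeline's own bandpass step is
nearly an identity on the generated series and does not distort the
correlation targets.

**What the generator does not emulate.** Gaussian edge noise instead of
the sampling distribution of Pearson correlations; no motion artifacts,
scanner drift beyond the band limits, hemodynamic response shape, or
spatial autocorrelation between neighbouring ROIs; block effects
independent across blocks; phenotypes generated directly from the target
correlation. Passing parameter-recovery tests therefore shows the
*analysis machinery* is correct and calibrated, not that it would behave
identically on real scanner data.

## Numerical choices

* **Filter realization.** Zero-phase forward–backward Butterworth
  band-pass of order 2 (effective order 4 after the two passes), designed
  by `signal::butter`. Zero phase avoids inter-ROI lag distortion that
  would bias Pearson correlations. Each series is demeaned and
  odd-reflection padded before `signal::filtfilt`, which on its own
  applies no end treatment and leaves large transients (a constant input
  came back with excursions of half its amplitude); with padding, DC maps
  to 0 and a 0.05 Hz probe is preserved to within 0.5%.
* **Vectorization order.** Row-major strict upper triangle. R's
  `upper.tri` indexing is column-major, so the implementation uses the
  transpose-and-lower-triangle identity; the ordering is asserted by test
  and recorded in output headers.
* **Ridge logistic fits.** `glmnet` with `alpha = 0`,
  `lambda = 1/(n * C)`, unstandardized features and an (unpenalized)
  intercept reproduces the C-parameterized penalized likelihood; this
  mapping is verified in the tests against direct BFGS minimization of
  the penalized log-loss to four decimals. The intercept is included
  because sign randomization balances the classes, leaving it near zero.
  Convergence threshold 1e-8, iteration cap 1e4. Single-feature fits pad
  a zero column (its ridge coefficient is exactly 0) because `glmnet`
  requires two columns.
* **Degenerate cases.** Zero-variance t-tests report p = 1 for a zero
  mean and a flagged p = 0 otherwise; single-class training draws are
  redrawn (logged); empty sphere masks and zero-variance ROIs propagate
  as flagged-missing edges, and a subject missing any edge of a block is
  excluded from that block's statistics; exact-zero sign counts get their
  own column; ranking ties break by block key order.
* **Voxel membership.** A voxel belongs to a sphere when its centre is
  within `radius_mm` (inclusive) of the ROI centre — deterministic and
  grid-resolution independent. Spheres may overlap; each ROI mean is
  computed independently.
* **Welch test.** The cross-sectional comparison uses the
  unequal-variance two-sample t-test because the emulated group sizes
  differ several-fold; both groups' dispersions and the pooled value are
  reported.

## Open design points, resolved

* **"SMT" in the headline block** is the somatomotor *hand* network
  (label 0); the 0–6 labeling of the effect refers to labels 0 and 6.
  A `merge_somatomotor` switch merges hand and mouth (labels 0 and 1)
  into a single SMT network for sensitivity analyses, giving 13 networks
  and 91 blocks.
* **Packaged atlas coordinates are synthetic.** Only the
  label-to-ROI-range structure of the 14-network grouping matters for
  block statistics, and that structure is packaged exactly; sphere
  centres are placeholders on a 12 mm grid (the filename says
  `synthetic`), and any user atlas in the same TSV format is accepted.
* **Frame count** is data-driven; the timeseries generator defaults to
  490 frames at TR 0.735 s (~6 minutes), a typical resting-state
  duration.
* **Problem sizes in the test-suite experiments** are the package's own
  choices: the longitudinal calibration runs on the two-network
  (somatomotor-hand + visual, 61-ROI) sub-atlas at the full n = 2,722,
  which preserves the headline block's exact edge count; the
  cross-sectional recovery on the 88-ROI somatomotor+default-mode
  sub-atlas at 5,000 per group; ranking recovery on a quarter-scale
  14-network atlas (56 ROIs — all 105 blocks present) with 600 subjects
  per run; and the null-calibration study on the same scaled atlas with
  50 subjects per seed across 200 seeds.

## Limitations

The generator's independence assumptions (edges within a block share only
the block effect; blocks independent) make Monte-Carlo standard errors
slightly optimistic relative to real FC, where edge noise is spatially
correlated. Cross-sectional and longitudinal generators share the
subject-level heterogeneity parameter even though real cross-sectional
variance has additional between-subject sources. The scan-order
classifier is linear; the package deliberately omits nonlinear
alternatives because the signed-difference representation already makes
the Bayes rule linear under the generator's Gaussian model.
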