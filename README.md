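# fclong — longitudinal functional connectivity over network blocks

Resting-state fMRI functional connectivity (FC) — the matrix of pairwise
Pearson correlations of BOLD signal between brain regions — changes subtly
as people age. With paired scans taken about two years apart, a small mean
change can be detected even when it is dwarfed by between-subject spread,
and it can be validated by asking whether a classifier can tell *which of
a subject's two scans is the later one* from the signed difference of
their FC. fclong packages that analysis for neuroimaging researchers:

* **FC construction** from 4D NIfTI volumes or ROI timeseries: mean BOLD
  within 5 mm atlas spheres, zero-phase Butterworth bandpass
  (0.01–0.15 Hz), Pearson correlation, and row-major upper-triangle
  vectorization (34,716 edge features for the packaged 264-ROI atlas);
* **network-block statistics**: with 14 functional networks there are 105
  blocks of edges; each block's average FC gets a per-subject
  older-minus-younger change, a cohort mean μ_Δρ, two dispersion
  summaries (per-subject block-change SD and mean per-edge change SD),
  and a Bonferroni-corrected two-sided one-sample t-test
  (p_bonf = min(1, 105 · p));
* **scan-order prediction**: sign-randomized FC differences with label
  s ∈ {−1, +1}, an L2-regularized logistic model at C = 1, learning
  curves over 20 random train/test splits, and a ranking of all 105
  blocks by single-feature accuracy;
* **cross-sectional comparison** of young (< 55) and old (> 65) groups
  with Welch t-tests, sign-count tables, and phenotype–change
  correlations;
* a **calibrated synthetic cohort generator** (FC-level and
  timeseries-level), because the longitudinal cohorts this analysis
  targets are access-restricted. Its defaults encode the headline effect:
  a somatomotor–visual (block 0–6) mean of 0.39 at the younger scan
  shifting by +0.03, against a per-edge change SD of 0.26.

## Worked example

```r
library(fclong)

# two-network sub-atlas (somatomotor hand + visual) at the full cohort size
atlas  <- atlas_subset(power264_atlas(), c(0, 6))
cfg    <- synth_config(atlas = atlas, n_subjects = 2722, seed = 1)
cohort <- generate_fc_cohort(cfg)
cohort_change_summary(cohort)
#> Longitudinal FC change over 3 blocks (2722 subjects)
#> Top 3 blocks by |t| (Bonferroni m = 3):
#>  key networks       mu sd_subject sd_edge_mean      t   p_bonf
#>  0-6  SMT-VIS  0.02837      0.108        0.259 13.708 6.25e-41
#>  6-6  VIS-VIS  0.00194      0.111        0.260  0.914 1.00e+00
#>  0-0  SMT-SMT -0.00120      0.110        0.260 -0.572 1.00e+00
```

The SMT-VIS block recovers the configured +0.03 mean change (μ_Δρ =
0.0284 ± 0.0021) with the per-edge change dispersion at the configured
0.26, and the change is overwhelmingly significant after Bonferroni
correction, while the unshifted within-network blocks sit at zero. The
same per-subject differences support scan-order prediction:

```r
samples <- make_diff_samples(cohort, feature = "0-6", seed = 1)
learning_curve(samples, train_sizes = c(500, 2000), reps = 20, C = 1, seed = 2)
#> Scan-order learning curve (feature: 0-6, C = 1, 20 reps)
#>  size accuracy
#>   500    0.597
#>  2000    0.599
```

Accuracy ~0.60 is exactly the Gaussian oracle Φ(μ/σ) for this block's
effect size (0.03 over a per-subject change SD of ~0.11) — the effect is
small per subject but reliably detectable. `rank_blocks()` repeats this
for every block and sorts; with a shift only in block 0–6 that block
ranks first.

See `vignettes/fclong-methods.Rmd` for the model, calibration choices and
numerical details, and `inst/cli/fclong.R` for a command-line dispatcher
over the same functions.

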