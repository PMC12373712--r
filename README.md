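# slmvpa

Searchlight multivoxel pattern analysis (MVPA) of simulated
motion-extrapolation fMRI experiments.

## What it is for

When a moving stimulus is occluded, early visual cortex continues to
represent the unseen trajectory. Studies of this effect use an
interception paradigm — a dot moves horizontally at a fast or slow speed,
turns up or down, and either stays visible or finishes behind an occluder
— and ask whether multivoxel patterns in retinotopic V1 and V5/hMT+
carry direction, velocity and congruency information, and whether a
classifier trained on visible motion transfers to occluded motion.

`slmvpa` implements that full analysis chain on synthetic data with
planted, recoverable ground truth, so every stage can be validated and
its statistical calibration measured. It is aimed at methodologists who
want a tested reference implementation of selection-plus-permutation
searchlight inference, and at analysts who want to rehearse this pipeline
against known truth before touching real scans.

The package provides:

* **Design generation** — interception-paradigm sessions with exact trial
  bookkeeping: 240 visible / 400 occluded trials over four runs, two
  direction–velocity run configurations, 30% incongruent trials in the
  low-predictability context exactly counterbalanced over cells (72/240,
  120/400), a fixed 0.716 s incongruent vertical duration, and integer
  Poisson inter-trial intervals in [2, 6] s.
* **BOLD simulation** — 4D volumes at TR = 2 s and 2.2 mm voxels in which
  each trial contributes `amplitude × pattern × canonical HRF`;
  per-condition multivoxel patterns inside synthetic lower-V1, upper-V1
  and V5 masks; a configurable visible↔occluded pattern correlation ρ; a
  spatially uniform trial-history increment on congruency-switch trials;
  AR(1) noise, cosine drift, random-walk motion parameters; and a tagged
  reappearance-responsive voxel subset that is excluded from decoding.
* **GLM estimation** — condition-wise OLS with the canonical HRF plus
  temporal and dispersion derivatives, motion and cosine-drift nuisance;
  single-trial betas by the least-squares-separate (LSS) scheme with a
  pooled other-trials regressor.
* **Searchlight decoding** — 4.4 mm spheres over ROI voxels, a
  shrinkage-regularized (Ledoit–Wolf) linear discriminant, balanced
  leave-25%-trials-out partitioning repeated four times, and cross-phase
  (train visible, test occluded) decoding.
* **Permutation inference** — the chance cutoff at 0.5, top-5%
  informative-sphere selection, within-run label permutation with
  per-iteration reselection, the (N + 1)-denominator group p-value
  `p = #{permuted ≥ true}/(N + 1)`, sphere-center overlap across analyses
  against a hypergeometric baseline.
* **Trial-history contrasts** — CC/CI/IC/II labeling of congruency
  transitions, repeated-measures ANOVA over the four categories and
  Bonferroni-corrected paired contrasts.

Everything is tibble-first: results are tibbles or small S3 objects with
`tidy()`, `glance()` and `autoplot()` methods, and `run_full_pipeline()`
chains the whole analysis with stage caching and TSV/NIfTI outputs.

## Worked example

One simulated subject, cross-phase decoding of motion direction (train
visible, test occluded) in the lower-V1 mask, with a planted
contrast-to-noise ratio of 1 and a shared-pattern correlation ρ = 0.7:

```r
library(slmvpa)

gm       <- generate_grid_and_masks(dims = c(12, 12, 12), seed = 1, n_voxels = 160)
effects  <- effect_spec(gm$masks, amplitude = 1, rho = 0.7, seed = 1)
noise    <- noise_spec(ar = 0.3, sd = 1, drift_amplitude = 0.5)

design_vis <- generate_design("HP", "visible",  seed = 1, n_runs = 2, trials_per_run_cell = 20)
design_occ <- generate_design("HP", "occluded", seed = 2, n_runs = 2, trials_per_run_cell = 20)
bold_vis   <- simulate_bold(design_vis, gm$grid, gm$masks, effects, noise, seed = 11)
bold_occ   <- simulate_bold(design_occ, gm$grid, gm$masks, effects, noise, seed = 12)

pat_vis <- extract_roi_patterns(fit_lss_betas(bold_vis, design_vis), gm$masks$lowerV1, design_vis)
pat_occ <- extract_roi_patterns(fit_lss_betas(bold_occ, design_occ), gm$masks$lowerV1, design_occ)
pat_vis
#> <pattern_set> lowerV1 (HP/visible): 80 trials x 144 voxels

spheres <- build_searchlights(pat_vis$voxels, gm$grid, radius_mm = 4.4)
map <- cross_phase_decode(pat_vis, pat_occ, spheres,
                          pat_vis$meta$direction, pat_occ$meta$direction,
                          seed = 21, analysis_id = "direction_visible_to_occluded")
glance(map)
#> # A tibble: 1 × 5
#>   analysis_id                   n_spheres mean_accuracy max_accuracy prop_above_chance
#>   <chr>                             <int>         <dbl>        <dbl>             <dbl>
#> 1 direction_visible_to_occluded       144         0.738        0.938             0.986

sel <- select_informative_spheres(map)
sel
#> <top_sphere_set> direction_visible_to_occluded: 7/144 spheres (of 142 surviving), mean accuracy 0.905

null <- subject_permutation_null(pat_vis, spheres, sel, pat_vis$meta$direction,
                                 n_iter = 99, seed = 31,
                                 test_patterns = pat_occ,
                                 test_labels = pat_occ$meta$direction)
group_level_p(sel$mean_accuracy, matrix(null, nrow = 1),
              analysis_id = "direction_visible_to_occluded")
#> <perm_null> direction_visible_to_occluded: true accuracy 0.905, p = 0 (conservative 0.01), 1 subjects, 99 iterations
```

Reading the output: 98.6% of spheres decode direction above chance across
the occlusion boundary (mean accuracy 0.738), the 7 most informative
spheres average 0.905, and none of the 99 within-run label permutations —
each re-run through the full searchlight-plus-selection analysis — reaches
the true value, so the literal permutation p is 0/100 (the conservative
variant, 1/100, is reported alongside). Note that the 0.905 is a
selection-inflated statistic: it is only interpretable against the
reselected permutation null, never against 0.5 directly.

A multi-subject study with group inference, trial-history contrasts and
TSV/NIfTI outputs is one call:

```r
res <- run_full_pipeline(pipeline_config(seed = 42, out_dir = "demo_out"))
res$report   # analysis_id, group accuracy, permutation p, sphere counts
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`.

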