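---
title: "Searchlight decoding of occluded motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight decoding of occluded motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slmvpa)
```

## The problem this package addresses

When a moving object disappears behind an occluder, early visual cortex
keeps carrying information about the unseen trajectory. Interception
experiments probe this by having observers judge where and when a dot will
reappear: the dot travels horizontally at a fast (0.250 s per segment) or
slow (0.450 s) speed, turns upward or downward, and — in the occluded
phase — finishes its vertical leg behind a rectangle. Speed predicts
direction within a session (two runs pair up-fast with down-slow, two pair
up-slow with down-fast), and in a low-predictability (LP) context 30% of
trials are *incongruent*: the vertical leg lasts a fixed 0.716 s instead
of the speed-congruent duration. A session comprises 240 visible-phase
trials or 400 occluded-phase trials over four runs, with integer
inter-trial intervals drawn from a Poisson law restricted to 2–6 s.

The analysis chain of interest asks where, within retinotopic V1 and
motion-sensitive V5/hMT+, multivoxel patterns discriminate direction,
velocity or congruency — and whether a classifier trained on the visible
phase transfers to the occluded phase, which would indicate a shared
representational format. `slmvpa` implements that chain end to end on
simulated data, so every step can be validated against planted ground
truth: design generation, BOLD simulation, condition-wise and
single-trial GLMs, ROI-restricted searchlight LDA, selection-based
permutation inference, and trial-history contrasts.

## The synthetic-data generator

`generate_design()` reproduces the trial bookkeeping exactly: cell counts
(30 visible / 50 occluded trials per direction–velocity cell per run),
exact counterbalancing of incongruent trials (18 per cell visible, 30 per
cell occluded), the 0.716 s incongruent vertical duration, and truncated
Poisson ITIs. Two readings of the printed timing are possible — whether
0.716 s covers the vertical segment alone or extends to the contact point
— and the generator takes the vertical-segment reading for both
incongruent cells. The Poisson law is read literally: integer draws from
Poisson(λ = 4), redrawn until they fall in [2, 6]; λ = 4 centres the
support and is the simplest rate matching the stated range. Run length is
the last offset plus 20 s of HRF decay room, in 2 s volumes.

`simulate_bold()` builds each voxel's time series as

    baseline + Σ_trials a_t · p_v(c_t) · h(t − onset_t) + drift + AR(1) noise

where `h` is a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6, 32 s support, unit peak) built at 0.1 s microtime and sampled
on the TR grid, `p_v(c)` is a per-condition spatial pattern drawn once per
region from a standard normal over mask voxels and z-scored, and `a_t` is
the planted amplitude. Because patterns are z-scored, a scalar amplitude
`a` with noise SD `σ` gives a single-trial contrast-to-noise ratio of
`a/σ` at mask voxels. Occluded-phase patterns are built as
`ρ·visible + √(1−ρ²)·independent` (then re-z-scored), so `rho` directly
controls how much cross-phase decoding is possible; the default 0.7
plants a clearly transferable but imperfect shared format. Trial-history
effects are planted as a *spatially uniform* amplitude increment on
congruency-switch trials (CI, IC), separate from the multivoxel pattern:
a z-scored pattern has zero spatial mean, so scaling it would be
invisible to the univariate ROI mean that the trial-history analysis
uses. Noise is AR(1) (default coefficient 0.3, marginal SD 1) plus an
optional slow cosine drift; motion parameters are six Gaussian random
walks (SD 0.01 per step) used as nuisance regressors only.

`generate_grid_and_masks()` synthesizes three compact, disjoint blobs
standing in for lower V1, upper V1 and V5 on an isotropic 2.2 mm grid,
with a contiguous 10% of each V1 blob tagged as responsive to the
stimulus reappearance; those voxels are excluded from every pattern
analysis, mirroring the exclusion applied to real data where reappearance
transients would confound decoding.

What the generator does *not* emulate: spatially correlated noise,
physiological fluctuations, motion-correlated signal, slice-timing or
susceptibility artifacts, subject-specific HRF variability, and any
behavioural data. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under a known forward model — not
that the scientific conclusions would replicate on real scans.

## GLM estimation

`build_design_matrix()` follows the standard informed-basis convention:
per condition, the onset stick convolved with the canonical HRF plus its
temporal and dispersion derivatives (finite differences at 0.1 s
microtime), then six motion columns, a DCT cosine drift basis up to a
128 s period cutoff, and an intercept. Only the canonical-HRF coefficient
is carried forward; derivative coefficients absorb onset and width
variability and are discarded.

Single-trial betas use the least-squares-separate (LSS) scheme with one
pooled "all other trials" regressor — the common two-regressor variant,
chosen over per-condition remainder regressors for stability at 60–100
trials per run. The fit is ordinary least squares with no prewhitening:
the simulation's noise autocorrelation is a known parameter, OLS keeps
the estimator exactly linear (so the noiseless oracle tests are exact),
and the permutation inference downstream does not rely on the GLM's error
model. Internally each trial's GLM is collapsed, after residualizing data
and trial regressors against the nuisance block once per run
(Frisch–Waugh), to an exact 2×2 solve — algebraically identical to the
naive per-trial fit but two orders of magnitude faster. Trials whose
onset leaves less than half the 32 s HRF support before the run end are
dropped with a logged count, since their betas would be systematically
biased. A caveat worth knowing: with a pooled-others regressor, LSS is
exactly unbiased only when the *other* trials share one amplitude at the
voxel; with heterogeneous amplitudes the pooled regressor is an
approximation, and the tests assert tight tracking (r > 0.999) rather
than exact recovery in that regime.

## Searchlight decoding

`build_searchlights()` centres a sphere at every retained voxel and takes
as members all retained voxels whose centre lies within 4.4 mm — 33
voxels for an interior centre at 2.2 mm resolution. The classifier is a
Fisher linear discriminant with equal priors whose pooled within-class
covariance is shrunk toward a scaled identity with the Ledoit–Wolf
analytic coefficient; with up to 33 features and ~48–60 balanced training
trials, unregularized LDA would be unstable or singular, and analytic
shrinkage makes every fit deterministic with no tuning loop. A
discriminant score of exactly zero resolves to the first class in sorted
label order, so reruns are bit-identical. When the within-class scatter
is exactly zero (degenerate inputs) the rule reduces to nearest-mean.

Partitioning is leave-25%-trials-out: trials are assigned to four folds
stratified by class (not by run — trials, not runs, are the
cross-validation unit here), each training split is balanced by randomly
subsampling the majority class to the minority count, and the whole
assignment is redrawn four times, giving 16 train/test splits whose
accuracies are averaged per sphere. Cross-phase decoding
(`cross_phase_decode()`) trains on one phase and tests on the other;
since the two sets are disjoint by construction there are no folds, and
the four repetitions come from redrawing the balancing subsamples on both
sides. Decoding one factor with the other collapsed (e.g., velocity with
directions pooled) is expressed simply by which label vector is passed.

The sphere-wise engine is compiled (RcppArmadillo): per split it computes
the class-centred Gram matrix over all retained voxels once and slices
each sphere's covariance out of it, which is what makes the permutation
null below affordable on one core.

## Selection and permutation inference

Per subject and analysis, spheres with accuracy at or below 0.5 are
discarded and the top 5% of the surviving distribution is retained
(round-half-up, floor of one sphere; boundary ties resolved toward the
lower centre index). The subject-level statistic is the mean accuracy
over the selected spheres. The group statistic averages subjects, and its
null distribution is built from label permutations: per iteration, labels
are shuffled independently *within each run* (respecting run-level
exchangeability), the partition scheme is redrawn, and the full
searchlight analysis is recomputed. The group null pools the per-iteration
subject averages, yielding N permuted group means plus the true one
(N + 1 values), and

    p = #{permuted group means ≥ true} / (N + 1).

This formula can return exactly zero; reports also carry the conservative
`(b + 1)/(N + 1)` variant, clearly labelled, without replacing the
primary formula.

One design question had to be settled empirically: what happens to the
top-5% *selection* under the null. Sampling the permuted maps at the
**fixed** centres selected from the true labels looks natural but is
circular — the true statistic is a maximum over the very map it was
selected from, while the fixed-centre null values are plain means, so on
completely signal-free data the group p collapses to ~0 essentially
always. `slmvpa` therefore **reselects** the top spheres on every
permuted map (same cutoff, same fraction), which subjects the null to the
same selection inflation as the true statistic; under this default the
rejection rate on signal-free data sits at the nominal 5% (the acceptance
suite verifies this over 100 independent 4-subject studies). The
fixed-centre variant remains available as
`subject_permutation_null(..., reselect = FALSE)` and a test documents
its anti-conservatism. A corollary worth stating plainly: the *absolute*
accuracies of selected spheres are selection-inflated (they exceed 0.5
even on noise), so they should be read against the permutation null, not
against chance.

`sphere_center_overlap()` counts shared selected centres across analyses,
with the hypergeometric expectation `k₁k₂/N` as the random-selection
baseline; overlap well above it indicates that different decoding
analyses converge on the same cortical sites rather than picking noise.
`paired_accuracy_test()` is a plain paired-t utility for comparing
per-subject accuracies between conditions; both sides share the selection
inflation, but the caveat above still applies to its absolute values.

## Trial-history contrasts

`label_trial_sequences()` labels every trial (except the first of a run)
with the (previous, current) congruency pair: CC, CI, IC, II. The
literature this mirrors is not perfectly consistent about whether the
first letter names the previous or the current trial; the pair-order
reading (first letter = previous trial) is used throughout and stated in
the documentation rather than silently resolved.
`history_contrasts()` averages ROI-mean single-trial betas into
subject × category cells, runs a one-way repeated-measures ANOVA over the
four categories — F on (3, 3(n−1)) degrees of freedom, no sphericity
correction (a documented limitation; with four levels and moderate n the
uncorrected F is mildly liberal) — and all six pairwise paired-t
contrasts with Bonferroni correction (p multiplied by 6, capped at 1).

## Numerical choices and reproducibility

* Microtime resolution 0.1 s for all HRF convolution; regressor columns
  agree with a direct-summation oracle to better than 1e−6 relative.
* All randomness descends from one integer seed through named
  sub-streams (`substream_seed()`), so regenerating one run's trial order
  never perturbs another run's noise, and every pipeline output is
  bit-reproducible from the configuration alone.
* The pipeline caches each stage under a hash of exactly the
  configuration fields that stage depends on; deleting a late stage's
  outputs never forces early stages to recompute.
* Degenerate cases are explicit: an all-below-chance map yields a flagged
  empty selection (never a silent zero); a permuted map with nothing
  above the cutoff contributes the cutoff value (0.5) to the null; a
  single-trial run falls back to a condition-style estimate with a
  warning; subjects missing a trial-history category are excluded with a
  warning.

## Known limitations

* **Cross-validated accuracy on temporally correlated betas is slightly
  pessimistic.** Adjacent single-trial betas share noise through HRF
  overlap and AR(1) errors; with 64–80 trials per subject the mean null
  map accuracy sits a few thousandths below 0.5 (on independent pattern
  matrices it is 0.500 exactly). This is a property of trial-wise
  cross-validation on fast event-related designs, not of the
  implementation; the permutation test is unaffected because true and
  permuted statistics share the bias.
* Selection inflation means per-subject "mean accuracy of informative
  spheres" is not an unbiased effect-size estimate.
* The RM-ANOVA applies no sphericity correction.
* The simulated problem sizes used in the test-suite (12³ grids, 160-voxel
  regions, 2-run sessions of 64–80 trials, 99 permutations, 100
  calibration repeats, 16-subject history studies) were chosen as the
  smallest sizes at which the studied effects are unambiguous; full-size
  sessions (4 runs, 240/400 trials, 1000 iterations) run with the same
  code paths.
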