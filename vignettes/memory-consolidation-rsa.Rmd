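---
title: "Measuring memory consolidation with representational similarity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring memory consolidation with representational similarity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memrep)
```

## The scientific question

Systems-level consolidation theory holds that autobiographical memories are
gradually reorganised into neocortex — in particular ventromedial prefrontal
cortex (vmPFC) — over months to years. If that is true, the *strength* of a
memory's neocortical representation should depend lawfully on the memory's
age, and re-measuring the same memories months later should find each
memory's representation at the strength appropriate to its *new* age.

`memrep` implements the full analysis pipeline for such a longitudinal
design, plus a synthetic-cohort generator so every stage can be validated
end to end without scan data.

## The design

Each subject selects 16 personal memories: two sets (A and B) of 8, one
memory per set at each of 8 ages — 0.5, 4, 8, 12, 16, 20, 24 and 60 months
old. During scanning every memory is recalled 6 times, giving 96 trials
split into 12 sessions of 8 trials. Two constraints shape the schedule:

* a memory is never recalled twice within a session (the score needs
  *cross-session* pattern similarity, which removes session-specific
  signal), and
* two memories of the same age are never recalled in the same session
  (so the matched-age baseline is never contaminated by shared session
  context).

`build_schedule()` satisfies both by alternating single-set sessions: each
session presents all 8 memories of one set in random order, and each set
appears in 6 of the 12 sessions. This layout is the simplest one that meets
both constraints exactly while balancing repetitions; `validate_schedule()`
re-checks the invariants on any schedule.

Trials rated below 3 on the 1–5 in-scanner vividness scale are excluded
(`filter_vivid_trials()`); a memory stays scorable only with at least two
retained trials in at least two distinct sessions.

## The neural representation score

For memory $m$, let $r^{within}_m$ be the mean Pearson correlation between
all cross-session pairs of $m$'s trial patterns, and let $r^{between}_m$ be
the mean cross-session correlation between $m$'s trials and the trials of
baseline memories. The score is

$$ s_m = r^{within}_m - r^{between}_m . $$

A positive score means the memory evokes a reproducible, memory-*specific*
pattern over and above generic retrieval activity. Two baselines are
provided: `"all-other"` (all other memories of the same set — the default,
using all available data) and `"matched-age"` (the identically aged memory
of the other set, controlling remoteness exactly). Raw correlations are
averaged without Fisher transformation; the score is a *difference* of
means of bounded quantities used in rank-based and t statistics, where the
transform changes nothing qualitatively. Scores are averaged over the (up
to) two memories per time point (`timepoint_scores()`), and time points
that lost a memory to vividness filtering are flagged, never silently
averaged away.

## The generative model

`simulate_subject()` draws, per subject,

* a unit-norm random *signature* vector per memory,
* one unit-norm *common retrieval* vector shared by all trials
  (weight `shared_component_weight`, default 0.2), and
* per-trial noise.

A trial's pattern is `amplitude(age) * signature + w * common + noise`.
The default amplitude profile `c(0, .6, .7, .9, .3, .1, 1.0, .9)` encodes
the hypothesised nonmonotonic consolidation time course: undetectable for
very recent (0.5-month) memories, rising to 12 months, dipping at 16–20
months, strong again for fully consolidated 24–60-month memories.

The noise is an equal-power mixture of a spatially smoothed Gaussian field
(Gaussian kernel, correlation length `spatial_corr_length = 2` voxels, rows
normalised so the marginal SD is preserved; 1-D by default, 3-D when
`dims` is given) and white noise. The white ("thermal") component matters
numerically, not just for realism: purely smoothed noise has a
near-singular covariance, and its inverse square root wildly amplifies
whatever lies in the low-variance subspace — during development this
inflated scores of *zero-amplitude* memories after whitening. Real scanner
noise always contains a broadband floor; including it keeps the covariance
well conditioned so whitening helps rather than hallucinates.

Vividness ratings are drawn with probabilities (.01, .03, .06, .35, .55)
for ratings 1–5, concentrating mass at 4–5 as real participants do, so the
default threshold of 3 removes a realistic ~10% of trials.

What the generator does *not* model: serial autocorrelation within the
BOLD time series (patterns are simulated directly at the trial level;
the GLM stage is exercised separately), physiological artefacts, motion,
inter-subject anatomical variability, and any dependence of noise on
signal amplitude. Scores recovered from it are therefore cleaner than real
data; its job is to make correctness and calibration testable, not to
predict empirical effect sizes.

## Pattern estimation and noise normalisation

`estimate_trial_patterns()` supports least-squares-separate (LSS: one GLM
per trial with a single "all other trials" regressor — the standard remedy
for collinear rapid designs) and least-squares-all (LSA). Regressors are
12-s boxcars convolved with the canonical double-gamma HRF on a 0.1-s grid.
Residuals always come from the LSA model, which spans all trials.

`estimate_noise_covariance()` averages per-session residual covariances
and shrinks toward the diagonal, with the analytic Ledoit–Wolf-style
`"auto"` rule (ratio of summed sampling variances of the off-diagonal
entries to their summed squares, clipped to [0, 1]; forced to at least 0.9
when residual rows are fewer than a tenth of the voxel count, where the
analytic estimate itself is unreliable). `whiten_patterns()` applies the
symmetric inverse square root, with eigenvalues floored at `1e-10` of the
maximum to keep the operation defined for rank-deficient inputs, and a
flag on the pattern matrix guards against accidental double whitening.

## Group inference

* `one_sample_t()` per time point: is the memory detectably represented?
* `rm_anova()`: does representation strength vary with memory age?
  Implemented over `car::Anova` (type III, within-subject design);
  Mauchly's test is computed for k > 2 conditions and, when it rejects at
  p < .05, both df are multiplied by the Greenhouse–Geisser epsilon —
  the classical SPSS-style convention. With k = 2, sphericity holds by
  construction and F equals the squared paired t. A zero effect sum of
  squares (identical conditions) is reported as F = 0, p = 1 rather than
  0/0. One caveat found while validating against a textbook oracle: R's
  Mauchly p value uses a variant of the second-order chi-square correction
  (k where the textbook has k − 1 in one factor); the two agree to about
  four decimals and the package inherits R's value.
* `two_way_rm_anova()`: experiment (original vs follow-up) x time point,
  fully within subject, per-effect sphericity handling.
* `paired_t_bonferroni()` for planned comparisons (optionally one-tailed
  per pair), `cousineau_sem()` for within-subject error bars, and
  `icc_absolute_single()` — ICC(2,1), two-way random, absolute agreement,
  single measure — for interrater reliability of detail scoring.

## The prediction-shift test

Eight months after the first experiment, every memory has aged by two
design time points. `shift_profile()` therefore predicts the follow-up
profile by reading the first experiment's scores at the shifted ages; new
ages beyond the last pre-remote sample (28, 32 months) are assumed to sit
at the 24-month value, and 60-month memories (68 at follow-up) are assumed
already stable. `directional_hypotheses()` turns the predicted-minus-
original differences into increase / decrease / no-change calls, treating
differences smaller than `tol` as no change. The default
`tol = 0.25 * range(profile)` mirrors how such predictions are read off a
profile plot by eye — differences well inside the plotting noise are not
honest directional claims; `tol = 0` recovers the strict sign rule. The
hypotheses are *data-driven from whatever profile is supplied*: the
direction set depends on the measured first-experiment profile, not on a
hard-coded list. `evaluate_predictions()` tests each call with a planned
paired t test (one-tailed where a direction is declared); a no-change call
is supported by non-rejection or, more stringently, by a TOST equivalence
test when `tost_bounds` is given.

## Searchlight and cluster inference

`grow_region()` grows a fixed-size region (default 160 voxels) around a
center by taking the nearest ROI voxels (Euclidean distance, ties broken
by linear index, so regions are deterministic); regions saturate with a
flag when the ROI is smaller than the target. `region_rsm_score()`
correlates (Spearman) the region's memory-by-memory RSM with the identity
model — within-memory cells above between-memory cells — by default
separately per memory set (averaged), since cross-set cells mix the
never-co-presented sets. `searchlight_map()` assigns each voxel the mean
score of every region containing it. `signflip_cluster_test()` performs
one-sample group inference by randomly sign-flipping whole subject maps
(the identity flip always included, so p ≥ 1/n_perm), thresholding t maps
at `t_thresh = 3`, and comparing observed 26-connected cluster sizes with
the permutation null of the maximum cluster size. An `exact = TRUE` mode
enumerates all 2^n sign patterns for small groups, which the test suite
uses to verify the sampled p values against complete enumeration.

## Problem sizes and runtime choices

The analysis drivers use 16 subjects, 60 voxels, whitening on — a few
seconds per script. Calibration tests use 1,000 null datasets (12 subjects,
16 voxels, shared schedule — the null distribution of the group t does not
depend on these sizes) and 500 sign-flip datasets of 1,000 permutations on
an 8×8×8 ROI with spatially smooth null maps; smoothness matters because
max-cluster-size is integer-valued and, on small ROIs with white noise,
its null is so discrete that size-based FWE control is badly quantised.
Recovery tests use 20 cohorts; all randomness is seed-derived and
bit-reproducible.

## Limitations

* The generator's omissions listed above; absolute score magnitudes are
  not comparable to empirical values.
* The HRF is fixed (no subject- or region-specific variation), and trial
  patterns in the simulator bypass the GLM rather than being generated as
  time series (the GLM stage has its own synthetic time-series tests).
* The pipeline assumes complete data (no missing sessions); memories lost
  to vividness filtering are flagged and excluded rather than imputed.
* Sign-flip inference assumes symmetric subject-map distributions under
  the null; cluster-size inference inherits the usual caveat that it
  licenses claims about clusters, not individual voxels.
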