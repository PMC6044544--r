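# memrep

Representational similarity analysis (RSA) of autobiographical memory
consolidation in ventromedial prefrontal cortex (vmPFC) — a tested R
pipeline with a synthetic longitudinal cohort generator.

## The problem

Systems-level consolidation theory predicts that a memory's neocortical
representation strengthens (and possibly fluctuates) lawfully as the
memory ages over months. Testing this requires (a) a per-memory,
per-subject measure of representational strength, (b) group statistics
over a repeated-measures design of 8 memory ages, and (c) a longitudinal
re-test: 8 months later every memory has aged by two design time points,
so the first measurement *predicts* the second.

The core statistic is the **neural representation score** of memory *m*:

```
s_m  =  r_within(m)  -  r_between(m)
```

where `r_within` is the mean Pearson correlation between all
*cross-session* pairs of `m`'s trial patterns and `r_between` is the mean
cross-session correlation with baseline memories (all other same-set
memories by default, or the identically aged memory of the other set).
`s_m > 0` means the memory evokes a reproducible memory-specific pattern
beyond generic retrieval activity.

The package covers the whole chain: schedule construction under the
design constraints (16 memories, 2 sets x 8 ages from 0.5 to 60 months,
6 repetitions, 12 single-set sessions of 8 trials, same-aged memories
never co-presented), trial-wise GLM pattern estimation (LSS/LSA) with
shrinkage noise-covariance whitening, vividness-based trial exclusion,
scoring, repeated-measures ANOVA with Mauchly/Greenhouse–Geisser
handling, the prediction-shift evaluation, and an ROI searchlight with
sign-flip cluster-level FWE inference. A generative simulator makes every
stage testable end to end; see the vignette
(`vignettes/memory-consolidation-rsa.Rmd`) for the model and the
reasoning behind parameter defaults.

## Worked example

The numbered scripts under `analysis/` run the study workflow end to end
and write tables to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort + design summary
Rscript analysis/02_score_memories.R     # per-subject scores, group profile
Rscript analysis/03_group_inference.R    # detectability + RM-ANOVA
Rscript analysis/04_prediction_shift.R   # 8-month follow-up evaluation
Rscript analysis/05_searchlight.R        # searchlight + cluster inference
```

With the default seed (42), 16 subjects and 60 voxels, the recovered
group profile tracks the ground-truth amplitudes:

```
time   mean_score  sem_within  truth_amplitude
0.5M      0.013      0.008        0.0
4M        0.475      0.007        0.6
8M        0.537      0.007        0.7
12M       0.646      0.009        0.9
16M       0.187      0.006        0.3
20M       0.049      0.009        0.1
24M       0.695      0.005        1.0
60M       0.639      0.006        0.9
```

Per-time-point detectability mirrors the expected structure — the
0.5-month memories are *not* detectable (t(15) = 1.53, p = 0.15) while
every older age is (e.g. 24M: t(15) = 101.9); the repeated-measures
ANOVA on memory age gives F(7, 105) = 1278, p < 1e-97.

In the follow-up arm (ground truth following the 2-time-point shifted
profile), the prediction-shift evaluation supports **8 of 8** directional
hypotheses, with a large experiment x time-point interaction
(F(7, 105) = 1724):

```
time   direction   t(15)      p   supported
0.5M   increase    57.75  2e-19   TRUE
4M     increase    16.76  2e-11   TRUE
8M     decrease   -21.99  4e-13   TRUE
12M    decrease   -43.04  2e-17   TRUE
16M    increase    56.64  3e-19   TRUE
20M    increase    90.45  3e-22   TRUE
24M    no_change    1.15   0.27   TRUE
60M    no_change    1.52   0.15   TRUE
```

The searchlight demo (signal confined to a 3x3x3 corner of a 6x6x6 grid,
10 subjects) recovers one significant cluster of 137 voxels
(p_FWE = 0.002), with mean map agreement 0.70 inside the signal block vs
0.15 elsewhere.

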