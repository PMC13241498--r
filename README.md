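# resplock

Tools for asking whether slow bodily rhythms shape bistable visual
perception. When observers view an ambiguous figure such as the Necker
cube, their percept flips spontaneously every few seconds. `resplock`
analyses co-recorded respiration, pupil size and reversal reports to
answer three questions:

1. **Do reversals align to the breathing cycle?** Respiration is coded as
   a linear phase (0 at peak inhalation, pi at the exhalation trough) and
   the event-locked phase-locking value

   `PLV(t) = | (1/N) * sum_i exp(1i * phi_i(t)) |`

   is tested against a circular-shift surrogate null with
   maximum-statistic correction over time. The epoch-count-unbiased
   pairwise phase consistency

   `PPC(t) = 2/(n(n-1)) * sum_{i<j} cos(phi_i(t) - phi_j(t))`

   is reported alongside as an effect size comparable across studies.
2. **Does pupil size change around a reversal?** Cleaned, z-scored pupil
   traces are epoched around each report and the group average is tested
   against zero with a cluster-based sign-flip permutation test
   (point-wise p < 0.05, clusters of >= 2 bins, max-|t| cluster statistic,
   cluster-level p < 0.01).
3. **What predicts percept stability?** Time-resolved linear mixed models
   predict the (log, mean-normalised) preceding or subsequent dominance
   duration — or pupil size — from respiration phase (sine + cosine),
   respiration frequency, pupil size, percept identity and the
   complementary stability, with random intercepts for participant and
   reversal number. Each predictor's evidence is the AIC difference
   between full and reduced models and its two-model Akaike weight
   `w = 1 / (1 + exp(-dAIC/2))` (dAIC = 9.2 -> w > 99%, dAIC = 6 -> ~95%).

A synthetic-data generator (`sim_config()`, `simulate_study()`) produces
respiration, pupil and reversal data with known ground truth — lognormal
percept-dependent dominance durations, ~3.76 s respiration cycles with
inspiration shorter than expiration, optional von Mises phase coupling of
reversals, a biphasic pupil kernel and blink gaps — so every stage is
validated by parameter recovery and null calibration in the test suite.

## Worked example

Simulate a small study with reversals coupled to respiration phase
(von Mises concentration 2) and run the full pipeline at reduced
surrogate/permutation counts:

```r
library(resplock)

cfg <- sim_config(n_participants = 8, n_trials = 2, coupling_kappa = 2,
                  seed = 42)
report <- run_pipeline(cfg, n_shifts = 400, n_permutations = 2000,
                       model_timepoints = seq(-2, 2, by = 1),
                       model_dependents = "pupil",
                       exclusion_bounds = c(1, Inf))
report
```

```
<resplock_report>
  participants kept: 8; reversals: 222 (75% isolated at +-2 s)
  best-fitting duration distribution: normal
<plv_surrogate> 8 participant(s), 400 surrogate shift(s)
  thresholds: p<0.05 at 0.3531, p<0.01 at 0.3894; observed max 0.7129
  p<0.05 window: -4.00 to 4.00 s
  p<0.01 window: -4.00 to 4.00 s
  mean PPC across participants: 0.3585 +/- 0.0168 (SEM)
<cluster_result> 8 participant(s), 2000 permutation(s), max statistic
  cluster -4.00 to -3.28 s: stat = 13.17, p = 0.007996 *
  cluster -2.92 to -1.43 s: stat = 17.11, p = 0.007996 *
  cluster -1.24 to 0.25 s: stat = 96.37, p = 0.007996 *
  cluster 0.30 to 2.42 s: stat = 62.11, p = 0.007996 *
  cluster 2.64 to 4.00 s: stat = 18.62, p = 0.007996 *
<model_comparison> dependent: pupil, 5 timepoint(s)
  percept_change         max delta AIC =    0.60 (weight 0.575)
  phase                  max delta AIC =  202.46 (weight 1.000)
  resp_freq              max delta AIC =   -1.38 (weight 0.334)
  stability_preceding    max delta AIC =  100.87 (weight 1.000)
  stability_subsequent   max delta AIC =   78.59 (weight 1.000)
```

Reading this output: the reversals were generated with strong coupling
(kappa = 2 corresponds to an event-phase PPC of `(I1(2)/I0(2))^2 ~ 0.49`),
and the observed group PLV (0.71 at its peak) exceeds the max-corrected
p < 0.01 threshold (0.39) — across the whole window here, because
respiration phase autocorrelates over the +-4 s epoch. The mean PPC of
0.36 is the planted effect size diluted by epoching away from the exact
event time. The pupil clusters before and after the reversal reflect the
planted constriction/dilation kernel (the central clusters carry by far
the largest statistics); the flanking clusters come from neighbouring
reversals a few seconds away, which is also why the *stability* terms
predict pupil size here — short preceding/subsequent stabilities put a
neighbour's kernel inside the epoch. The mixed models recover the planted
respiratory modulation of pupil size (decisive dAIC for the joint
sine/cosine phase term) while the unplanted respiration-frequency and
percept terms stay near dAIC 0. At this small pooled sample (222
durations from two percept-specific lognormals, perturbed by the
phase-coupling jitter) AIC happens to rank the normal family first; on
>= 1000 uncoupled durations the generating lognormal wins essentially
always (asserted in the test suite).

Individual stages are plain functions over data frames —
`preprocess_respiration()`, `detect_cycles()`, `assign_phase()`,
`interpolate_blinks()`, `detrend_exponential()`, `epoch_around_events()`,
`plv_timecourse()`, `ppc_timecourse()`, `plv_surrogate_test()`,
`cluster_permutation_test()`, `build_design_table()`,
`fit_stability_models()` — and every result object supports `tidy()`,
`glance()` and `autoplot()`.

## A note on scope

The package analyses pre-recorded, uniformly sampled traces in tabular
form (`time_s`, `value`). Hardware acquisition, eye-position analysis,
luminance modelling and spectral/cross-frequency coupling measures are out
of scope. See the methods vignette
(`vignettes/resplock-methods.Rmd`) for the full account of the models,
conventions and design decisions.
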