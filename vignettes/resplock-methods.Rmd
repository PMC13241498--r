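---
title: "Methods: linking respiration phase, pupil size and perceptual reversals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking respiration phase, pupil size and perceptual reversals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resplock)
```

## The analysis problem

When observers view a bistable figure such as the Necker cube, their
perception alternates spontaneously between two interpretations, reported
here by button presses. `resplock` implements a three-part analysis of how
these reversals relate to two slow physiological signals recorded
alongside: the respiration cycle and pupil size.

1. **Event-locked phase statistics.** Is the respiration phase at which
   reversals occur more consistent than chance? Quantified by the
   phase-locking value (PLV) with a circular-shift surrogate null, and by
   the pairwise phase consistency (PPC) as an unbiased effect size.
2. **Event-locked pupil dynamics.** Does pupil size deviate from baseline
   around a reversal? Tested with a cluster-based sign-flip permutation
   test of the group-average event-locked trace against zero.
3. **Predictors of percept stability.** Do respiration phase, respiration
   frequency and pupil size carry information about how long a percept
   lasted (or will last)? Assessed with time-resolved linear mixed models
   compared by AIC differences and Akaike weights.

Because every stage makes detailed processing choices, the package ships a
synthetic-data generator with *known* ground truth, so that each stage is
validated by parameter recovery rather than by eyeballing.

## Respiration preprocessing and phase coding

The raw respiration trace is band-pass filtered (third-order Butterworth,
high-pass 0.03 Hz, low-pass 6 Hz), resampled to 100 Hz and z-scored over
the whole recording. Filtering is applied forward and backward
(`signal::filtfilt`) because phase is the quantity of interest and a
causal filter would shift it. The trace is demeaned before filtering so
the slow high-pass sees no DC step at the edges.

Inhalation peaks are local maxima of the z-scored signal exceeding
z = 0.5, with a minimum separation of 1.5 s (a physiological bound, under
40 breaths/min, that suppresses double detections on noisy plateaus).
Peak and trough times are refined by a local quadratic fit (+-0.35 s);
the raw argmax of a flat breath apex wanders by more than a sample under
measurement noise, and the vertex of the fitted parabola is a better
estimate of the true apex. Each cycle spans trough-to-trough around its
peak, and a fixed 7-s waveform snippet centred on the peak (edge-padded
with missing values) is kept for quality control: cycles whose mean
squared distance to the pointwise-mean centroid exceeds the across-cycle
mean by more than 3 SD are flagged atypical and excluded from phase
assignment. Pairwise exclusion of the padded samples keeps edge cycles
from being auto-rejected.

Phase is coded linearly in time with anchors at the physiologically
meaningful reference points: 0 at the inhalation peak and pi at the
exhalation trough, so the descending (expiration) half of the signal maps
onto [0, pi) and the ascending (inspiration) half onto [pi, 2*pi). For a
cosine-shaped breath this makes the signal equal to cos(phase) exactly,
which is also how the generator constructs its traces — ground-truth phase
is exact by construction and the estimate can be scored against it (the
test suite requires a circular mean absolute error below 0.25 rad at
default noise). Samples inside breathing-pause plateaus (absolute slope
below 5% of the cycle's peak slope for more than 250 ms — thresholds are
our choice, the convention only says such pauses carry no defined phase),
inside atypical cycles, or outside any cycle remain unassigned and are
excluded per-sample downstream. The respiration frequency before an event
is the mean instantaneous frequency (1/duration) of the last two completed
cycles; a one-cycle variant exists for sensitivity checks and correlates
highly with it on simulated data.

## Pupil preprocessing

Blinks (missing runs) are extended by a 100 ms guard margin on each side —
eyelid-closure ramps contaminate neighbouring samples — and linearly
interpolated. Slow drift is removed by subtracting a least-squares
exponential fit `a*exp(b*t) + c`; the fit profiles the sum of squares over
the decay rate `b` alone (the model is linear in `a` and `c` given `b`),
which always converges and needs no start values. The detrended trace is
low-pass filtered at 8 Hz (zero-phase), resampled to 100 Hz, and z-scored
within the recording; the z-scored trace is what all downstream models
see. The order interpolate -> detrend -> filter -> resample -> z-score is
fixed. Epochs are not baseline-corrected: the cluster test is against
zero on the z-scored trace, so a nonzero epoch-mean level is part of what
is being tested.

## Event-locked epochs and phase statistics

Epochs span -4 to +4 s around each reversal at 100 Hz (801 samples);
events whose window is not fully inside the recording are dropped and
counted. At each epoch time `t`, with `n` epochs carrying an assigned
phase,

* `PLV(t) = |mean_i exp(1i * phi_i(t))|` — the resultant length, in
  [0, 1]; biased upward at small `n` (expectation `sqrt(pi)/2/sqrt(n)`
  under uniform phases);
* `PPC(t) = 2/(n(n-1)) * sum_{i<j} cos(phi_i(t) - phi_j(t))` — the mean
  pairwise cosine, unbiased in `n` and usable as an effect size across
  studies.

The implementation computes PPC through the exact algebraic identity
`PPC = (n*PLV^2 - 1)/(n - 1)` (O(n) per timepoint); the O(n^2) pairwise
sum is kept in the test suite as an oracle and the two agree to 1e-10.

Significance of the group-average PLV uses a surrogate null: per
iteration, every participant's continuous phase series is circularly
shifted by an independent uniform offset and epochs are re-cut at the
original event times. Shifting the whole series (rather than each epoch
independently) preserves the within-recording phase autocorrelation and is
the stricter null. The maximum of the group-average PLV over the whole
grid is recorded per iteration, and the 95th/99th percentiles of these
maxima give thresholds corrected for multiple comparisons over time
(default 4000 iterations). Internally the shift-and-re-epoch loop is
evaluated with one FFT cross-correlation of the complex phase series with
the event indicator per participant — numerically identical to explicit
shifting (asserted in the tests) and fast enough to calibrate the null by
simulation: with no coupling, the p < 0.05 threshold is exceeded in ~5% of
runs.

## Cluster-based permutation test

Participant-wise event-locked pupil averages enter a one-sample test
against zero: point-wise t-tests (two-sided, since both constriction and
dilation are hypothesised) thresholded at p < 0.05; runs of at least two
suprathreshold bins form clusters; the cluster statistic is the maximum
|t| inside the cluster ("maximum as cluster statistic" is read as max
statistic, not max size; a summed-mass variant is available via
`statistic = "mass"` for sensitivity analysis). The null flips the sign
of each participant's whole trace (20000 permutations by default), and a
cluster's p-value is `(1 + #{null maxima >= observed}) / (n_perm + 1)`,
never exactly zero. Clusters with p < 0.01 are flagged. Because sign
flips leave each column's sum of squares unchanged, the permutation null
reduces to one matrix product plus a vectorised run scan, making the
family-wise-error calibration (500 simulated null datasets at 2000
permutations) affordable in the test suite.

## Time-resolved mixed models

For each reversal and each epoch lag (default -4 to +4 s in 0.2 s steps),
a design row holds: the preceding and subsequent percept stabilities
(divided by the participant's mean, then log-transformed), respiration
frequency (z within participant), pupil size at the lagged time (z within
participant), the sine and cosine of respiration phase at the lagged time,
and the percept change as a two-level factor coded by the destination
percept. Models are fit by maximum likelihood (required for AIC
comparisons across fixed-effect structures) with random intercepts for
participant and for reversal number, where reversal number is interpreted
as the within-recording ordinal of the reversal (the terse "#reversal"
notation admits a per-trial reading; the ordinal is the default here).
Respiration phase is tested by removing sine and cosine jointly, because
its predictive power is shared between the two terms; each other predictor
is removed alone. Evidence is `delta AIC = AIC(reduced) - AIC(full)` and
the two-model Akaike weight `1/(1 + exp(-delta/2))`: a difference of 9.2
corresponds to a weight above 99%, a difference of 6 to about 95%.
Slope p-values use the normal approximation on t = beta/SE; with the row
counts involved (thousands) the approximation is immaterial, and the AIC
comparison, not the per-term p, is the primary criterion. Timepoints with
non-converged fits yield missing values; rows with unassigned phase or
missing pupil at a lag are dropped at that lag only.

## Behavioural quality control

Stabilities are within-trial successive differences of report times;
intervals never span the inter-trial gap, and the first percept of a trial
contributes no duration. Participants reporting more than 900 or fewer
than 120 reversals are excluded (boundary counts are kept — the rule is
strictly "more than"/"fewer than"). Dominance durations are fit by
maximum likelihood with gamma, lognormal, Weibull, exponential and normal
families and ranked by AIC (`2k - 2 log L`), pooled across participants
and also participant-wise. A +-2 s purity window optionally restricts
epochs to reversals with no neighbouring report. Simple group tests
(paired t of left vs right stability, first vs second half counts,
correlation of reversal count with peak phase coherence) complete the
report.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 75 s trials with 15 s rest,
left-percept dominance 4.73 +/- 1.79 s and right 3.16 +/- 1.23 s
(lognormal, moment-matched), respiration cycles 3.76 +/- 0.73 s
(lognormal) with inspiration occupying 1.71/3.76 of the cycle, and a
biphasic pupil kernel (Gaussian constriction lobe, amplitude -0.3 z at
-0.5 s, width 0.4 s; dilation +0.4 z at +1.0 s, width 0.6 s) on top of an
exponential baseline drift, a cosine modulation of pupil size by
respiration phase (gain 0.2 z, maximal at peak inhalation), white noise
(SD 0.1) and blink gaps (15/min, mean 150 ms, encoded as missing runs,
never zeros). Traces are cos(phase) of a piecewise-linear phase, so the
generator's phase is exact ground truth. One global seed determines
everything; per-participant streams are derived by fixed offsets.

Where the study conditions leave the mechanism open, choices are flagged:

* **Event-phase coupling.** No generative recipe exists for *how*
  reversals would couple to respiration phase. The generator draws a
  target phase from von Mises(mu, kappa) and moves the tentative reversal
  to the nearest later time attaining that phase. We initially tried
  rejection sampling of candidate times against the von Mises density,
  but candidate phases are not uniform a priori (successive durations are
  comparable to the cycle length), which attenuates the realised
  concentration by ~40%; the draw-then-match construction makes reversal
  phases von Mises *exactly*, so the expected PPC equals the squared
  Bessel ratio `(I1(k)/I0(k))^2` and coupling strength is a usable ground
  truth. The jitter is bounded by about one cycle, so the marginal
  duration distribution is only slightly perturbed.
* **What the generator does not emulate:** gaze position, saccades,
  luminance, pupil foreshortening, oral-breathing artefacts, response
  latency between internal reversal and button press, or any real-data
  non-stationarity beyond the exponential pupil drift. Passing recovery
  tests therefore validates the estimators and their calibration, not the
  physiological claims themselves.

## Numerical choices and degenerate inputs

* Zero-variance traces cannot be z-scored and raise errors; all-missing
  pupil traces raise errors; fewer than 5 cycles skip atypical-cycle
  rejection with a warning; fewer than 5 participants refuse the cluster
  test; fewer than 2 usable events drop a participant from phase locking
  and the design table.
* Repeated filtering is near-idempotent in the passband; exact
  idempotence is impossible for finite recordings because the 0.03 Hz
  high-pass has edge transients and the z-score renormalises, so the
  tests check interior samples at a 1% level instead.
* Permutation and surrogate p-values are lower-bounded away from zero by
  the `+1` convention.
* Event-locked kernel amplitudes are measured against the epoch-average's
  own tail baseline (|lag| >= 3 s): the detrend constant absorbs the mean
  level of event-locked activity, shifting the whole average by the mean
  kernel integral per unit time.

## Problem sizes in the test suite

Simulation-based checks use deliberately scaled problem sizes chosen for
statistical decisiveness: surrogate-null calibration uses 200 simulated
studies of 20 participants at 400 shifts; cluster family-wise error uses
500 null datasets at 2000 permutations; the mixed-model null battery uses
20 seeds at an 0.8 s model grid; distribution selection uses >= 1000
durations (where AIC picks the generating lognormal essentially always).
The full-scale defaults (4000 shifts, 20000 permutations, 0.2 s grid)
remain the analysis defaults in `run_pipeline()`.

## Known limitations

* Phase coding is piecewise-linear between detected extrema; within-half
  nonlinearity of real airflow is not modelled.
* The surrogate shift is uniform over the full recording; a lag-restricted
  variant is not implemented.
* Only time-domain clustering is provided (no multi-channel clustering).
* Random slopes are not supported in the mixed models, and per-term
  p-values are normal-approximate.
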