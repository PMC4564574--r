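---
title: "Methods: task-evoked pupillometry in cognitive-control tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-evoked pupillometry in cognitive-control tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilflow)
library(dplyr)
```

pupilflow analyzes task-evoked pupillary responses (TEPRs) recorded while
participants perform three classic cognitive-control tasks: a 2-Back
(working-memory updating), a color-word Stroop (inhibition) and a Number
Switch task (set shifting). The pupil dilates transiently after a
cognitively demanding stimulus, and both the amplitude of that response
and its relation to behavior carry information about how much processing
resource a participant allocates. This vignette documents the measurement
model, every tunable parameter that matters, the synthetic-data generator
the test suite exercises, and the numerical conventions, so that results
are interpretable without reading the source.

## Signal model and preprocessing

The input is a Tobii-style binocular sample stream at a nominal 60 Hz:
per-sample timestamps (ms), left/right pupil diameter (mm) and per-eye
validity flags. Preprocessing proceeds in fixed order:

1. **Eye combination** (`combine_eyes()`). The analyses use a single
   diameter signal. A sample is *missing* when the tracker marked the left
   and/or right eye invalid; otherwise the diameter is the mean of the two
   eyes. The disjunctive missing rule is deliberately conservative: a
   sample backed by only one valid eye is treated as an artifact, never as
   half a measurement. The mean-of-both-eyes rule itself is a documented
   package choice — tracker vendors do not standardize it — and matters
   little downstream because baseline correction removes any constant
   between-eye offset.
2. **Artifact padding** (`pad_missing()`, default 3 samples ≈ 50 ms per
   side). Blink onsets and offsets corrupt a few samples around the run the
   tracker flags; every sample within 3 samples of a missing one is
   therefore also marked missing. Padding twice with *p* equals padding
   once with 2*p*, and the interpolated count is monotone in the pad — both
   are property-tested.
3. **Linear interpolation** (`interpolate_linear()`). Each missing run
   bounded by valid samples is filled with the straight line through its
   two anchors, computed against real timestamps so irregular sampling is
   tolerated. Runs touching a trace boundary have one anchor only and are
   filled by holding the nearest valid value; this keeps epochs rectangular,
   and such samples still count toward exclusion fractions, so trials
   dominated by them are dropped anyway. Originally valid samples are
   never altered.

## Epoching, baseline and trial exclusion

Epochs are cut from −500 to +3000 ms around stimulus onset
(start-inclusive, end-exclusive). The span is a package choice: it must
contain the 500-ms pre-stimulus baseline, every task's summary window and
the late condition differences seen in waveform contrasts; overlap with
the next trial (inter-trial interval 2000 ms) is harmless because analyses
only read defined windows. *Dilation* is diameter minus the mean diameter
in the 500 ms before onset, computed per trial; the baseline mean of the
corrected signal is zero to 1e-9 by construction, and adding any constant
to the raw trace leaves dilation unchanged.

A trial is excluded when **more than 70%** of the samples in its baseline
interval and/or its summary window were interpolated (post-padding); a
fraction of exactly 0.70 is kept, matching the strict "more than"
semantics. The stricter 0.50 variant is available via
`apply_exclusion(threshold = 0.5)` but discards many more trials, making
individual-difference measures noisier. Interval membership everywhere is
start-inclusive, end-exclusive on sample timestamps, with a 1e-6 ms guard
so samples nominally on a bound (60 Hz timestamps are not exactly
representable in floating point) fall on the same side regardless of
rounding history.

The per-task 500-ms summary windows default to 1100–1600 ms (2-Back),
1000–1500 ms (Stroop) and 1300–1800 ms (Number Switch). `select_window()`
reproduces how such windows are chosen — among windows containing the
grand-average peak, maximize mean |t| of the condition contrast (or mean
dilation for a single-condition task), ties resolved by larger mean
dilation and then earliest start — but routine analyses use the fixed
defaults.

## Waveform statistics and the cluster rule

Condition waveforms are averaged per subject over included, correct trials
(error-related analyses opt out of the correctness filter), then compared
across subjects with a paired two-tailed t-test at every sample
(df = n−1). A zero-variance difference with non-zero mean is reported as
p = 0 (the limiting case); identically zero differences give t = 0, p = 1.
To control the multiplicity of testing every sample, an effect is reported
only where p < 0.001 over **at least six contiguous samples** (100 ms at
60 Hz). Cluster bounds are the times of the first and last member sample.
Cluster detection is tested against a brute-force run scanner and is
invariant under monotone transformations of p that preserve the threshold
crossing. No permutation-based cluster-mass correction is implemented —
the contiguity rule is the method under study.

## Behavioral indices

- **2-Back** (`score_2back()`): trial *t* is a match when its letter equals
  the letter at *t*−2 within the same block; the first two trials of a
  block have no referent and are excluded from error and RT denominators (a
  package choice; the design leaves them undefined). Every trial is also an
  encoding trial: `encoding_ok(t)` is the correctness of the response at
  *t*+2.
- **RT floor**: RTs below 300 ms are removed for the 2-Back and Number
  Switch tasks; exactly 300 ms is kept; the Stroop task is exempt.
- **3-SD trial trim** (`filter_rt_sd()`): for Stroop and Number Switch,
  correct-trial RTs deviating more than 3 SDs from their subject-by-condition
  cell mean are flagged in a single pass (reference statistics computed
  before any flagging). Trimming within subject × condition is a package
  choice: pooled trimming would confound subject speed differences with
  trial exclusion.
- **Between-subject outliers** (`subject_outliers()`): subjects more than
  3 SDs from the across-subject mean on a measure are flagged *for that
  measure only*, preserving power on every other measure.
- **Error counts** are right-skewed; `sqrt_transform()` normalizes them
  before correlation/regression.
- **Stroop effect**: mean correct incongruent RT minus mean correct
  congruent RT, and the incongruent-minus-congruent error-percentage
  difference. **Switch cost**: the same construction on mixed-block trials,
  where a trial is a switch trial when its cue color differs from the
  previous trial's; the first trial of each mixed block has no predecessor
  and enters neither category (treating each mixed block as its own
  sequence is a package choice — a block break interrupts the trial
  stream). The correctness side of the switch cost is computed as a rate
  difference, not a count difference.
- Omitted responses (no key press within 1500 ms for the 2-Back, 3000 ms
  otherwise) are scored as errors: stimuli stay up until a response or the
  deadline, so an omission is a performance failure.

## Between-subject statistics

`correlation_matrix()` reports Pearson r with two-tailed p per pair under
pairwise deletion, because subjects are excluded per measure.
`stepwise_forward()` builds a parsimonious model by repeatedly entering
the candidate with the smallest F-change p while that p is below the
entry threshold (default 0.05; 0.10 is accepted via `entry_alpha` since
reported non-entries are typically stated only as p > 0.10). Predictors
and response are z-scored, so coefficients are standardized betas; each
predictor is also reported with its squared zero-order correlation, which
for a one-predictor model equals beta². When any two candidates correlate
above 0.90 in absolute value the fit is refused with a multicollinearity
diagnostic — with near-duplicate predictors (inter-predictor r around
0.95) unique contributions are indiscernible and zero-order correlations
are the honest summary. `paired_contrast()` is the two-level
repeated-measures ANOVA, F = t² with df = (1, n−1) and partial eta squared
F·df1/(F·df1 + df2); it is asserted against the sample-wise paired t
cross-module.

## The synthetic-study generator

No raw dataset accompanies the design, so the package ships a generator
(`simulate_study()`) whose defaults *are* the study conditions, enabling
parameter-recovery testing of every stage:

- **Designs**: 2 × 45 2-Back trials with exactly 34 match trials (17 per
  block by default; the global count is the documented constraint, the
  split is configurable), built so that no accidental extra matches occur;
  3 Stroop blocks of 18 congruent + 18 incongruent trials from the 3 × 3
  word/ink set; 2 pure + 2 mixed Number Switch blocks of 32 trials with
  parity-in-yellow / magnitude-in-blue rules. Inter-trial interval 2000 ms;
  response deadlines 1500/3000/3000 ms. Generated designs always pass
  their own constraint rescans.
- **Pupil trace**: subject baseline (N(4.5, 0.4) mm) plus, per trial, an
  amplitude times a unit-peak gamma-shaped kernel
  (t/t_max)^n · exp(n(1 − t/t_max)) with shape 10.1; time-to-peak defaults
  (1350/1250/1550 ms per task) sit inside each task's summary window so the
  defaults exercise those windows. AR(1) noise (φ = 0.95, innovation SD
  0.010 mm) adds temporally correlated measurement error; each eye gets
  independent N(0, 0.01 mm) sensor noise.
- **Amplitudes** default to the group descriptives they emulate: 0.098
  (2-Back), 0.110/0.152 (congruent/incongruent), 0.131/0.171
  (non-switch/switch) mm, plus a subject effort shift (0.06 mm per SD of a
  latent trait θ_s), a condition-specific subject deviation (SD 0.03 mm), a
  trial deviation (SD 0.05 mm) and a 0.08 mm increment on error trials.
  This makes between-subject SDs and cross-condition correlations land
  near the descriptives they are calibrated to.
- **Blinks**: Poisson onsets at 0.4/s with geometric run lengths of mean
  500 ms, invalidating both eyes. These values were calibrated once so
  that post-padding trial retention under the 0.70 rule is about 73%,
  the retention the method is designed around.
- **Behavior**: lognormal RTs with condition-specific means (623/705,
  1110/1279, 742 ms), between-subject spread 0.12 and trial spread 0.25 on
  the log scale, truncated at the deadline (a too-slow draw becomes an
  omission, scored as an error). Error probability is
  logistic(b_c − 0.2·θ_s) with intercepts solved for the target mean rates,
  so higher-effort subjects both dilate more and err less. The slope 0.2
  sets the generating correlation between mean dilation and error count to
  about −0.5, the coupling strength the recovery tests target. A
  consequence worth knowing: the simulated between-subject spread of error
  rates is narrower than real cohorts show — matching that spread would
  roughly double the dilation–error correlation — so the generator
  prioritizes the coupling over the marginal variance.

What passing tests show, and do not show: the recovery suite demonstrates
that the pipeline detects condition effects where they are simulated,
rarely reports clusters under a null, and recovers a built-in
dilation–performance coupling. It does not validate the measurement model
against real eye-tracker output — gaze-dependent foreshortening, luminance
responses, slow vigilance drifts and non-stationary blink behavior are all
absent from the generator (the isoluminant-stimulus design the tasks
assume removes the luminance component by construction, not by modeling).

## Problem sizes used by the test suite

The acceptance checks run at sizes chosen to make Monte-Carlo conclusions
stable while keeping the suite routine to run: the null cluster-rate check
uses 200 single-block Stroop studies of 15 subjects with the blink process
off (the false-positive rate of the cluster rule does not depend on the
blink process, and a reduced design sharpens nothing but the clock);
effect recovery uses 20 full-design Stroop studies of 35 subjects with
blinks on; coupling recovery uses one 200-subject 2-Back study; the
end-to-end determinism check runs the full 35-subject, three-task default
once. Each simulated subject-task pair flows through the identical
exported pipeline functions a real dataset would.

## Numerical conventions and degenerate inputs

- Interval membership: start-inclusive, end-exclusive, 1e-6 ms edge guard.
- Zero-variance paired differences: p = 0 when the mean difference is
  non-zero, p = 1 otherwise; `paired_contrast()` marks such results
  degenerate rather than guessing.
- Zero-SD trimming cells and zero-SD outlier screens flag nothing.
- An epoch with an empty baseline interval is dropped with a reason; an
  all-missing trace is an unrecoverable error; a window containing no
  samples is an error, not a silent zero.
- All randomness flows from one root seed; per-subject streams are derived
  from it, so identical seed and configuration reproduce every output file
  byte for byte.

## Known limitations

- The eye-combination rule and the boundary-hold interpolation are
  documented choices where tracker vendors and the design leave the
  behavior open; both are exercised by tests, but other reasonable choices
  (single-eye fallback, spline interpolation) are not implemented.
- `stepwise_forward()` implements forward entry only — no backward
  elimination — matching how parsimonious models are reported in this
  literature.
- The generator couples effort to amplitude linearly; saturation or
  inverted-U resource allocation cannot be simulated.
- Waveform statistics assume a shared sample grid across subjects, which
  regular-rate recordings provide; recordings with heavy clock drift would
  need resampling upstream, which the package does not perform.
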