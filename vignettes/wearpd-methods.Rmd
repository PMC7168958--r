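---
title: "Methods: simulating and classifying parkinsonian motor symptoms from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying parkinsonian motor symptoms from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wearpd studies how data-measurement choices — which inertial sensors to
record, at what sampling rate, and which engineered features to compute —
affect the accuracy of machine-learning detection of Parkinson's disease
tremor and bradykinesia from a hand-worn sensor and a wrist smart watch.
Because the corresponding clinical recordings are access-restricted, the
package pairs the analysis pipeline with a synthetic-cohort generator whose
defaults emulate the clinical study design, so that every stage is testable
end to end and the qualitative findings can be reproduced as controlled,
seeded experiments.

This vignette documents the models, conventions, and design decisions. It
states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The synthetic cohort

The generator (`generator_config()`, `generate_dataset()`) emulates a
clinic protocol: 13 participants perform 13 standardized motor tasks, 7
repetitions each. Repetition 1 is done medication-OFF (maximal symptoms);
repetitions 2–6 follow a dose at successive intervals with severity
declining along a per-participant medication-response curve; repetition 7
is a second-visit ON assessment. Two devices record simultaneously: a
skin-mounted hand sensor (tri-axial accelerometer ±4 G and gyroscope
±1000 deg/s at 62.5 Hz) and a wrist watch (accelerometer only, nominal
50 Hz). Recording lengths are uniform on 15–60 s.

**Latent severities and clinician scores.** Each participant carries latent
tremor and bradykinesia propensities on the clinical 0–4 scale, drawn from
a mild-to-moderate mixture (a majority mild, a minority up to 2.9, so score
4 is never emitted — matching the absence of score-4 clips in clinic data
of this kind). A clinician-style score for a given task performance is

    score = clamp(round(propensity × task_expression × medication_response + noise), 0, 4)

with Gaussian scoring noise (SD 0.25, truncated at ±0.49 so rounding can
move a score at most one step). `task_expression` encodes that rest and
postural tremor is fullest during low-movement holds and partially
suppressed by voluntary action, while bradykinesia is most visible in
fine-motor and clinical-assessment tasks; this within-participant
modulation is what gives every participant a mixture of score-0 and
symptomatic clips, as a real rating session would. Three low-movement tasks
do not involve enough movement to rate bradykinesia and yield no
bradykinesia annotations, so bradykinesia-scored clips are systematically
fewer than tremor-scored ones. The propensity mixture and expression
factors were calibrated once against the published score distribution of
the clinical cohort this design emulates (about three quarters of
tremor-scored clips at score 0, with frequencies decreasing 1 > 2 > 3) and
then frozen.

**Kinematics.** Ideal hand motion is synthesized on a dense 200 Hz grid as
a sum of:

* a gravity projection under slow orientation drift (sinusoidal angle
  drift at 0.03–0.12 Hz) — this is what the 0.5 Hz high-pass later removes;
* a voluntary oscillation at the task's base frequency (0–5 Hz, the band
  of ordinary human movement) with a mild second harmonic;
* a tremor sinusoid with frequency drawn uniformly from 4–6 Hz — the
  characteristic parkinsonian band — amplitude set by the tremor score
  (0 m/s² at score 0, rising to 8 m/s² at score 4), slow amplitude
  modulation at 0.25 Hz, and a random fixed orientation across axes;
* white process noise.

Bradykinetic slowing multiplies the voluntary component's speed and
amplitude by a per-score factor (1, 0.8, 0.65, 0.5, 0.35), with an
additional within-recording amplitude decrement proportional to score
(slowness with progressive decrement is the defining feature of
bradykinesia). Angular velocity is built from the same oscillatory phases,
so the gyroscope always carries the full slowing signature; the share of
the slowing expressed in the accelerometer is a config exponent
(`brady_accel_coupling`, default 0.4). Setting it to 0 yields the
"slowing encoded chiefly in angular velocity" regime used to probe the
sensor-set comparison; the default leaves a partial accelerometer
signature, consistent with gyroscope-inclusive models holding an edge for
bradykinesia while accelerometers suffice for tremor.

**Sensor model.** Each device samples the ideal motion at its nominal rate
with Gaussian timestamp jitter (SD 2 ms), drops each sample independently
(3%), adds sensor noise, and clips to the device range. The watch signal is
the same hand motion attenuated by 0.85 (wrist placement) with its own
independent noise and no gyroscope — a deliberate simplification that
preserves the empirical finding that hand and wrist accelerometers carry
similar information. Acceleration is stored in G, angular velocity in
deg/s; `g_to_ms2()`/`ms2_to_g()` convert.

**What the generator does not emulate.** Real biomechanics (limb inertia,
task-specific movement trajectories), pharmacokinetics beyond a monotone
multiplier, clinician inter-rater structure, freezing of gait, rigidity,
dystonia, and bilateral effects are all out of scope. Passing tests
therefore show that the pipeline recovers structure the generator encodes,
not that the models would reach any particular accuracy on clinical data.
The scoring-noise term is a free parameter, not an estimate of clinician
noise.

## Preprocessing

The chain is strictly `regularize → downsample → highpass → segment`
(`preprocess()` enforces the order):

1. **Regularization.** Device timestamps are jittered and samples drop out,
   so every recording is cubic-spline interpolated to its nominal rate over
   the recorded span (no extrapolation). Fewer than 4 samples is an
   unusable recording. The original timestamps are kept as a sidecar for
   the validity rule.
2. **Downsampling** (`resample_poly()`). Rational-ratio polyphase
   resampling: zero-insertion upsampling, a linear-phase FIR low-pass
   designed with `signal::fir1` (20·max(p,q)+1 taps) at the smaller Nyquist
   frequency, then decimation. The long filter matters: it is what
   suppresses a 4–6 Hz tremor once the target Nyquist falls below the
   tremor band, the mechanism behind the sampling-rate results. The
   shipped `signal::resample` was not used because its short filter leaves
   a large fraction of out-of-band tone power in place.
3. **High-pass.** Accelerometer channels only, 4th-order Butterworth at
   0.5 Hz applied forward–backward (zero phase, so clips stay aligned with
   their labels), with odd-reflection padding of 6/cutoff seconds to tame
   the edge transient of the gravity step. Gyroscope channels pass through
   untouched. The unfiltered accelerometer channels are retained — see the
   magnitude convention below. Filtering precedes segmentation so 5-s
   windows carry no per-clip filter transients.
4. **Segmentation.** 5-s windows with 50% overlap: `floor(5 × rate)`
   samples per window (312 at 62.5 Hz — the 0.5-sample truncation is a
   ≤0.5% window-length error), hop of half a window. A clip is valid iff
   the un-interpolated data contain at least 80% of the expected
   `5 × nominal_rate` raw samples within its time span; invalid clips are
   excluded from modeling. Clips inherit the recording's symptom scores
   unchanged.

## The feature set

74 features per sensor modality per clip — 57 tri-axial and 17
magnitude-based — in five categories; both modalities give 148:

| Category | Per axis (x, y, z) | Magnitude | Features |
|---|---|---|---|
| T (time) | 18 | 6 | RMS, range, mean, variance, skew, kurtosis |
| F (frequency) | 18 | 6 | dominant frequency, relative magnitude, PSD moments (mean, SD, skew, kurtosis) |
| E (entropy) | 3 | 1 | sample entropy |
| C (correlation) | 6 | 0 | cross-correlation peak and lag for XY, XZ, YZ |
| D (derivative) | 12 | 4 | moments of the first difference × rate |

Conventions, uniform across categories:

* **Moments** are population moments; kurtosis is excess kurtosis; a
  zero-variance signal has skew 0 and kurtosis 0 by convention.
* **PSD** is a Hann-windowed periodogram of the mean-removed clip (a Welch
  estimate with one full-length segment; at 312 samples, averaging
  segments would trade too much resolution). The "PSD moments" are
  spectral moments — moments of frequency under the normalized PSD viewed
  as a probability mass (the centroid family) — which are scale-invariant
  and standard in activity recognition; moments of the PSD ordinates would
  scale with signal power, duplicating the time-domain variance.
* **Relative magnitude** (not further defined in the source literature) is
  the power in the dominant bin and its two immediate neighbors over total
  power. The ±1-bin main lobe matters because a Hann-windowed tone that
  falls between bins splits its power across two bins; the single-bin
  fraction of a pure tone can drop to ~0.66 while the 3-bin fraction stays
  near 1.
* **Sample entropy** uses the de-facto standard m = 2, r = 0.2 × clip SD
  (population SD), Chebyshev distance, matches counted with ≤ r,
  self-matches excluded, both template counts ranging over the N − m
  windows that admit an (m+1)-length extension. When either count is zero
  the value is undefined and is capped at log((N−m)(N−m−1)). The kernel is
  the O(W²) double loop in C++; an independent brute-force R implementation
  serves as the test oracle.
* **Cross-correlation** is the zero-padded linear cross-correlation of
  mean-removed axis pairs over all lags, normalized by the product of the
  axes' root energies; the peak is its maximum and the lag is the signed
  peak position in seconds, ties broken toward the smallest absolute lag.
  A zero-variance axis yields peak 0, lag 0.
* **Derivative** features use the forward difference scaled by the rate
  (the scheme is not pinned down in the source literature; forward
  differencing is the simplest consistent choice).
* **The accelerometer magnitude channel is the norm of the *unfiltered*
  signal.** The Euclidean norm is orientation-invariant by construction,
  which is the field's reason for computing magnitude features at all, so
  it does not need the orientation-removing high-pass. The gravity
  baseline inside the norm is also what keeps oscillatory power at the
  oscillation frequency: |g + a(t)| ≈ |g| + a∥(t) linearizes, whereas the
  norm of a zero-mean oscillation is a rectification that folds a 5 Hz
  tremor to 10 Hz and would break the tremor-band interpretation of the
  magnitude spectrum. Axis features use the high-passed channels.
* Gyroscope channels are never high-pass filtered (angular velocity has no
  gravity offset); gyro features are computed on the
  regularized/downsampled signal directly.

Feature names are `modality_source_category_statistic`
(e.g. `accel_mag_F_dom_freq`) in a stable canonical order. The
magnitude-only variant keeps the 17 magnitude features plus the six
tri-axial correlation features, which have no magnitude counterpart
(23 per modality).

**Computation-time measurement.** `time_feature_sets()` times actual
extraction of each category combination over a fixed clip batch (median of
repeated runs). Shared preliminaries — the FFT behind frequency features,
the differencing behind derivative features — are computed once per
combination, so costs are subadditive. Timing is hardware-dependent;
analyses use only its rank structure, never the millisecond values, and
measured ties at timer resolution are perturbed deterministically (see the
Pareto rule below).

## Models and evaluation

Probability random forests (`ranger`, 50 trees, remaining hyperparameters
at library defaults, fixed seed, single-threaded for determinism) classify
each clip. Binary models code a symptom present at clinician score 1–4 and
absent at 0; multiclass models predict the 0–4 score. Clips without a
bradykinesia score are excluded from bradykinesia models.

Evaluation is leave-one-participant-out (LOPO): one fold per participant,
all of a participant's clips (including overlapping windows) on one side.
Overlap is not leakage under LOPO because folds split by participant, and
all preprocessing is per-recording, so no training-fold statistic ever
touches the held-out participant. Binary folds are scored with the
concordance-probability AUROC (midranks; ties count ½ — the trapezoidal
ROC area). Multiclass folds are scored one-vs-rest per class present in
the fold's test labels, averaged with test-set prevalence weights
renormalized over the present classes; classes absent from a test set
(score 4 never occurs) are skipped. The weighting scheme is a documented
choice — the source convention says only "weighted average". A binary fold
whose held-out participant shows a single class has no defined AUROC; it
is marked unevaluable with a warning and dropped from that comparison's
fold set (handling of such folds is not specified in the source
literature). Fold summaries report the mean with a 95% t-interval across
folds.

## The three experiments

All comparisons are paired by fold (the left-out participant), and each
comparison matrix is complete: a fold unevaluable under any condition is
dropped from all conditions.

* **Sensor sets** (`sensor_set_experiment()`): Combo (148 hand features),
  Accel (74), Gyro (74), Watch (74 wrist accelerometer features).
* **Sampling rates** (`sampling_rate_experiment()`): the device ladder
  62.5, 50, 40, 30, 20, 10, 7.5, 5 Hz (the watch ladder starts at 50),
  re-running downsample → high-pass → segment → extract at each rate, with
  the sensor set fixed per symptom (Accel for tremor, Combo for
  bradykinesia, following the sensor-set result).
* **Feature categories** (`feature_set_experiment()`): at a 30 Hz working
  rate, all 31 non-empty category subsets are timed and scored, then the
  Pareto discard rule drops any subset that fails to beat every cheaper
  subset's mean AUROC. The retained frontier strictly increases in both
  time and AUROC; AUROC comparisons are at full floating precision
  (displayed tables round). The magnitude-only variant repeats this with
  the 23-feature set.

**Statistics.** The omnibus test is a one-way repeated-measures ANOVA with
folds as subjects: F = MS_condition / MS_(fold×condition) on (k−1,
(n−1)(k−1)) degrees of freedom, computed in closed form and cross-checked
in the tests against `aov(y ~ cond + Error(subj))`. No sphericity
correction is applied (none is used in the source analysis; with it,
borderline p-values would grow). Post-hoc paired t-tests run only when the
ANOVA is significant at α = 0.05, exactly the planned set: one-tailed
Combo > each other set plus two-tailed Accel vs Watch for sensors;
one-tailed original rate > each lower rate; one-tailed costliest retained
feature set > each other retained set. Families are Holm–Bonferroni
corrected at family-wise α = 0.05 (`stats::p.adjust`). Zero-variance
difference vectors get a documented sentinel (t = 0, p = 0.5/1 when the
common difference is 0; ±Inf with p = 0/1 otherwise).

## Problem sizes and reproducibility

The generator's defaults are the full study conditions (13 participants ×
13 tasks × 7 repetitions, 15–60 s recordings). The replicated experiment
checks in the test suite and the acceptance script run on a reduced cohort
the package treats as its standard small design: 7 participants, a
5-task battery spanning all archetypes (including one unscorable postural
hold), 3 repetitions, 15–18 s recordings, with 10 generator seeds and a
majority-pass criterion for stochastic orderings (the acceptance script
averages 5 replicate cohorts). The rate experiments there use the
62.5/30/5 Hz rungs of the ladder — the top, the sufficiency point, and the
sub-Nyquist rate — which carry the whole qualitative contrast. The
score-distribution calibration is checked on the full default cohort,
whose annotations are cheap to generate.

Everything is deterministic given a configuration: dataset generation is a
pure function of `generator_config()` (including its seed), forests are
seeded and single-threaded, and `run_study()` stamps outputs with a config
hash so a rerun reproduces every artifact byte-identically except the
wall-clock timing column of `pareto.csv`.

## Known limitations

* Synthetic kinematics are stylized; absolute AUROCs on this data say
  nothing about clinical performance — only the orderings and mechanisms
  (aliasing, sensor information content, cost/accuracy trade-offs) are
  meaningful, which is why acceptance is property-based.
* The strong default effect sizes place several models near the AUROC
  ceiling, compressing condition differences; the constructed regimes
  (e.g. `brady_accel_coupling = 0`) exist to de-compress the contrasts
  under study.
* Timing ranks depend on implementation language and hardware; with the
  entropy kernel in C++ the entropy category still dominates single-category
  cost, but the margins are machine-dependent.
* The cli surface is the package API plus `run_study()`; there is no shell
  entry point, as the intended users drive analyses from R.
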