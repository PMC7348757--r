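---
title: "Classifying attention states from in-ear EEG with echo state networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying attention states from in-ear EEG with echo state networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sustained attention can be monitored from EEG because attentive and resting
states modulate oscillatory power in characteristic frequency bands —
classically, alpha (8–13 Hz) power rises when a subject disengages and rests,
while theta and gamma activity accompany task engagement. In-ear EEG, recorded
from electrodes molded to the ear canal, makes such monitoring wearable: two
channels (left and right ear), modest signal quality, 250 Hz sampling.

`earesn` implements a complete offline pipeline for discriminating
*attentive* from *resting* states in two-channel recordings collected under a
visual vigilance protocol: runs of 8 self-paced trials, each preceded by a
pre-stimulus fixation interval of 6 ± 2 s during which the subject is
attending and not moving (so the segment is free of keypress artifacts),
followed by a 48 s rest block per run. The classifier is a leaky echo state
network (ESN) over band-wise spectral/temporal features of 0.5 s epochs, with
a ridge-trained linear readout, sign-threshold classification, and causal
moving-average smoothing of the readout.

Because no public recordings exist for this protocol, the package ships a
first-class synthetic-data generator that emulates the statistical structure
the analysis relies on. Everything downstream is therefore testable end to
end without any download, and the generator's assumptions are documented
here so it is clear what passing tests do — and do not — establish about
real data.

## The synthetic session generator

`make_session_schedule()` lays out the timeline: per run,
`trials_per_run = 8` attentive pre-stimulus intervals with duration drawn
uniformly in [4, 8) s, each followed by an unlabeled 1.5 s stimulus/response
gap, then one 48 s rest block. The protocol specifies a nominal 6 s fixation
interval jittered by a random amount below 2 s, which is ambiguous between a
one-sided and a symmetric jitter; the generator draws uniformly over the full
[4, 8) s interval, which covers both readings, and exposes the bounds in
`session_config()`. The
stimulus/keypress period between fixation and the next trial is not part of
the protocol description; the generator inserts a configurable 1.5 s
unlabeled gap there, and those samples are excluded from epoching (mirroring
the use of pre-stimulus data only).

`synthesize_recording()` builds each channel as an additive, within-state
stationary process:

* **Background**: 1/f pink noise (exponent 1), standard deviation 60 µV,
  correlated 0.6 across the two channels (a shared-plus-individual mixture).
* **Band components**: one random-phase sinusoid per canonical band, centered
  in the band, with baseline peak amplitudes delta 20, theta 10, alpha 15,
  beta 5, gamma 2 µV, multiplied per sample by a state-dependent factor.
* **Attention effect** (the planted signal): alpha ×1.8 at rest, theta ×1.3
  and gamma ×1.2 during attention, everything else ×1. These magnitudes are
  free parameters of the generator, chosen once to give a separable but
  non-degenerate task (within-subject accuracies land around 0.9, not 1.0);
  they are not claims about physiological effect sizes.
* **Subjects**: each subject's band baselines are perturbed once by a
  log-normal factor (scale 0.1), supporting cross-subject validation with
  inter-subject variability.

Reaction times are truncated-normal draws (mean 0.4 s, SD 0.05 s) with a 5%
false-start probability (replaced by a uniform draw below 0.1 s) and a 5%
lapse probability (uniform in 1–2 s). These rates feed the exclusion rules
below; they are plausible for rested adults on a vigilance task and are
configurable.

What the generator does **not** model: eye-blink/EMG artifacts, electrode
impedance drift, event-related potential morphology, nonstationarity within
a state, or narrowband components with realistic bandwidth (the sinusoids
are perfectly coherent). Passing the end-to-end tests therefore shows the
pipeline recovers a planted band-power contrast under 1/f noise — it does not
certify performance on real in-ear recordings.

All randomness flows from integer seeds through `derive_seed()`, a string
hash that expands one user seed into independent per-stage, per-subject,
per-fold and per-repeat streams; identical configurations reproduce results
byte for byte.

## Features

Per recording: the continuous signal is bandpass filtered 1–50 Hz with a
6th-order Butterworth filter applied forward and backward (zero phase), then
cut into non-overlapping 0.5 s epochs (125 samples at 250 Hz) inside each
labeled interval; windows that would span a label change, and intervals
shorter than one window, are dropped, so every epoch is a full single-state
window. "6th-order" follows the MATLAB/Octave `butter(6, [low high])`
bandpass convention (12 poles). The filters are designed and applied in
second-order sections (cascaded biquads): a 12-pole bandpass whose low edge
sits near DC is numerically unusable in single transfer-function form at
250 Hz — its output is dominated by rounding noise — while the biquad cascade
is stable and makes the whole feature path exactly scale-equivariant.
Zero-phase filtering uses odd-reflection edge padding with steady-state
initial conditions, so start-up transients are negligible even on short
windows (a constant input yields its steady-state output from the first
sample).

Per epoch and channel:

* **Spectral (1 per band)**: a single-segment short-time Fourier transform
  with a Hamming taper and no zero padding (2 Hz bin spacing at 0.5 s),
  converted to a one-sided PSD; the feature is the mean over band-interior
  bins (center frequency in [low, high)) of the *square root* of the PSD.
  Summing instead of averaging over bins is available as a switch; averaging
  is the default so bands with different widths are comparable.
* **Temporal (5 per band)**: the epoch is filtered with each band's
  6th-order zero-phase Butterworth bandpass, then mean amplitude, standard
  deviation, peak-to-peak, skewness and kurtosis of the filtered window are
  computed. "Mean amplitude" of a zero-mean band-filtered window is taken as
  the mean of absolute values (the signed mean would be ≈ 0 and
  uninformative); the signed variant is available as a switch. Kurtosis uses
  the Pearson convention (normal → 3). A constant filtered window has
  undefined skewness/kurtosis; both are returned as 0 and flagged.

For two channels and five bands this gives 10 spectral + 50 temporal = 60
features, ordered channel-major and named `<channel>_<band>_<statistic>`.
Attentive epochs are labeled +1, rest epochs −1.

`fit_standardizer()` / `apply_standardizer()` z-score each feature and then
map the training minimum/maximum of the z-scores to −1/+1. The statistics
are computed on **training rows only** and frozen: computing them on all
data would leak test information into cross-validation. Test rows may land
outside [−1, 1]; they are not clipped. Zero-variance features get unit
standard deviation and a flag rather than a division by zero.

## The classifier

The reservoir state follows the leaky-integrator recursion

$$x(t) = (1 - \alpha)\,x(t-1) + \alpha \tanh\!\big(W^{in} u(t) + W\,x(t-1)\big),$$

with leaking rate $\alpha \in (0, 1]$ and tanh activation. $W$ (N × N) has a
fraction $c$ of nonzero entries, drawn uniform in [−0.5, 0.5] and rescaled so
its largest eigenvalue magnitude equals the target spectral radius $\lambda$;
$W^{in}$ is uniform in $[-\sigma, \sigma]$. Both are fixed at construction;
only the readout is trained. The readout is linear on the concatenation of
input and state,

$$y(t) = W^{out}\,(u(t), 1, x(t)),$$

with an intercept realized as a constant-1 input component (the protocol
description is silent on a bias term; a linear readout without one cannot
shift its decision threshold, so the component is included and documented).
$W^{out}$ solves the Tikhonov-regularized normal equations with
$\beta = 10^{-8}$ — small enough to behave like least squares while avoiding
its numerical instabilities. The regularizer penalizes all coefficients
including the bias, which is immaterial at this $\beta$. Output feedback is
not used. Positive readouts classify as attentive, negative as resting; an
exact zero goes to resting (the conservative class for an attention monitor,
and a measure-zero event).

**Sequence handling.** Consecutive epochs of one contiguous segment — a
run's attention stream or a rest block — form one input sequence, and the
state resets to zero at segment boundaries. Carrying state across a
run/rest boundary would leak label information at test time. In the pooled
k-fold scheme the training subsequence of each segment (test epochs removed,
time order kept) forms the training sequence and the test subsequence the
test sequence, so test rows never influence training states; this is what
makes the leakage canary below pass bitwise.

**Defaults and ranges.** N = 100 internal units, connectivity c = 0.1,
$\alpha$ = 0.3, $\lambda$ = 0.9, $\sigma$ = 1 (on features already rescaled
to [−1, 1]), washout 0 (configurable). The grid search optimizes $\alpha$
over (0, 1] and $\lambda$ over (0, 2], both in steps of 0.1 (200
combinations), each combination evaluated with 10 independently seeded
reservoirs; $\lambda$ slightly above 1 can win in practice, which is why the
grid extends to 2. Reservoir sweeps cover N = 10…100 by 11 connectivities
(110 configurations) and N = 100…1000 at c ∈ {0.01, 0.1} (20
configurations).

**Smoothing.** `smooth_readout()` replaces each output by the causal mean of
itself and the n − 1 previous outputs (every available output near the start
of a trace), n ∈ 1…12, i.e. 0.5–6 s. Smoothing never crosses segment
boundaries. `smoothing_curve()` re-thresholds stored cross-validation traces
per window without retraining.

## Evaluation

Attended trials with reaction times below 100 ms (false starts) or above
mean(RT) + 3 sd(RT) (lapses) are excluded; the statistics are computed per
subject over all trials before any exclusion (the order of operations is
otherwise unspecified), rest epochs are never excluded, and exclusion
precedes every cross-validation split.

Three schemes, mirroring the protocol's validation designs:

* **Within-subject** (leave-one-run-out): fold i tests on run i — its
  attention stream plus the rest block that follows it (the pairing of rest
  blocks to runs is a package choice) — and trains on the rest.
* **Cross-subject** (leave-one-subject-out): one fold per subject.
* **k-fold** (pooled, k = 10): epochs from all subjects are randomly
  partitioned into balanced folds regardless of run boundaries. Temporally
  adjacent epochs can then fall on opposite sides of a split, which makes
  this scheme optimistic relative to the run-held-out ones; that optimism is
  inherent to the design and documented rather than patched.

Per fold, the standardizer, the grid search and the readout see training
rows only. Grid-search selection uses mean training-side classification
accuracy over the repeats (an SSE switch exists); selection by training
accuracy is optimistic but matches reporting maximum training accuracy
alongside test accuracy. Ties break toward smaller $\lambda$, then smaller
$\alpha$ — the more contractive, more stable reservoir. The grid search is
re-run per fold (stricter than once per subject).

A canary test guards the leakage contract: multiplying all test-fold feature
rows by 1000 must leave every fold's standardizer, grid table and trained
readout *bit-identical*.

## Numerical choices and degenerate inputs

* Spectral-radius rescaling tolerance 1e-6; an all-zero or nilpotent
  recurrent draw (possible at tiny N·c) is resampled with an incremented
  seed and a warning.
* Reservoir states stay in (−1, 1) after the first update from a zero start
  (tanh range, $\alpha \le 1$); the echo state property is checked
  empirically (trajectories from different initial states converge below
  1e-3 over 500 steps for $\lambda \le 0.95$).
* Ridge is solved via the regularized normal equations on the concatenated
  design; at $\beta = 10^{-12}$ it matches QR least squares to 1e-6 on
  well-conditioned designs.
* Epoch/label boundaries use one shared sample-index arithmetic
  (`round(t × fs)`), so label painting and epoching can never disagree.
* Schedules with zero runs, empty input sequences, single-trial RT vectors
  (lapse rule disabled), and constant filtered windows all have defined,
  tested behavior rather than NaNs.

## Problem sizes used by the tests and the acceptance script

Unit tests run on deliberately small sessions (2–4 runs of 3–4 trials,
shortened rests) chosen so the full suite exercises every code path in a few
minutes. The end-to-end checks and `scripts/acceptance.R` use the full-sized
protocol — six subjects, runs of 8 trials with 6 ± 2 s intervals and 48 s
rests at 250 Hz — with 6 runs per subject (the low end of a typical session)
and a 3 × 3 hyperparameter subgrid (one reservoir per combination) for the
cross-validated accuracies; these sizes are the package's chosen benchmark
configuration,
keeping the script's runtime in minutes while preserving the protocol's
structure. On this synthetic benchmark the pipeline typically reports
within-subject accuracies in the mid-0.9s, k-fold slightly lower, and
cross-subject lower still (the planted per-subject amplitude perturbations
make transfer harder) — the same ordering the real-data protocol reports,
though the absolute numbers are properties of the generator, not of any real
recording.

## Known limitations

* The generator's stationary sinusoid-plus-pink-noise model is far simpler
  than real in-ear EEG; accuracies on it say nothing quantitative about
  hardware recordings.
* Grid search scored by training accuracy is optimistic; a nested validation
  split would be slower but less biased (the `statistic` switch and per-fold
  re-search make this easy to change).
* The pooled k-fold scheme inherits temporal leakage by construction, as
  discussed above.
* EDF support is the classic 16-bit format with one fixed record duration;
  annotations and per-channel rates are out of scope (labels live in
  delimited sidecars).
* Training is offline batch ridge; no online/recursive least squares.
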