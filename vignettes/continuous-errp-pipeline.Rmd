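---
title: "Detecting error-related potentials during continuous feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting error-related potentials during continuous feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a person notices an error — their own, or one made by an interface they
are operating — a stereotyped EEG deflection, the error-related potential
(ErrP), appears over frontocentral electrodes. In brain-computer-interface
(BCI) work ErrPs are a free supervision signal: detect them and you can
correct or adapt the decoder. Almost all of that work relies on
*time-discrete* feedback, where the moment at which an error could occur is
known and a classifier can be locked to it. This package addresses the
harder continuous-feedback setting, modelled on a video-game task in which a
subject steers a cursor while blocks fall from the top of the screen. Two
error families occur:

* **execution errors** — the interface corrupts the subject's control: the
  cursor's movement angle is perturbed by 45°, 90°, 180°, 270° or 315° for
  2 s, with consecutive perturbations separated by a uniform 5–8 s gap
  (measured here from the end of one perturbation to the onset of the next);
* **outcome errors** — the goal fails: the cursor collides with a block
  (sparse, on the order of 86 per hour).

The pipeline answers three questions on data with this structure: can the
two ErrP families be measured and distinguished; can they be classified
single-trial, both event-locked and *asynchronously* (sliding over the
continuous record with no event marker); and does error severity (the
perturbation angle) leave a decodable trace.

Because no public recording with usable identifiers exists for this task,
the package is driven by a first-class synthetic-data generator that
emulates the recording conditions, and every claim the test suite makes is
a claim about recovery of known ground truth from that generator.

## The synthetic session model

`simulation_config()` / `generate_recording()` produce a continuous session
with the montage used downstream: 28 scalp EEG channels (Fpz … O2, the
10-20-style set with FCz/Cz present), 3 EOG channels, and a 2-D thumbstick
trace, all at 512 Hz. The signal is a sum of four components:

1. **Background EEG.** Each channel is an AR(4) process driven by white
   noise, scaled to 10 µV standard deviation, with coefficients
   (0.5, 0.15, 0.05, 0.02) chosen to give a moderate 1/f-like spectrum.
   Spatial correlation is induced by mixing a common AR process into every
   channel (ρ = 0.5). A steeper background (near-unit-root AR) was
   considered and rejected: it concentrates essentially all power below
   4 Hz, which both exaggerates the delta-band background beyond what a
   0.5–60 Hz band-passed recording shows and buries the delta/theta error
   response that the asynchronous detector must find.
2. **Error responses.** Each event injects a deterministic waveform — a sum
   of signed Gaussian bumps — plus stochastic band-limited delta (1–4 Hz)
   and theta (5–7 Hz) noise bursts, all projected through a frontocentral
   topography that is maximal at FCz/Cz. The execution template has peaks
   (+) 229 ms, (−) 287 ms, (+) 367 ms, (−) 461 ms; the outcome template
   (−) 2 ms, (+) 268 ms, (−) 486 ms, (+) 742 ms, broader and stronger.
   Peak amplitudes (5.5–6.5 µV execution, 7–9 µV outcome at FCz) and burst
   strengths (≈3–4.5 µV sd) were fixed once so that canonical ERP practice
   works on the generator: averaging ≥ 200 epochs recovers the template
   with correlation above 0.9, and the delta/theta response is strong
   enough at `snr_scale = 2` for near-ceiling recovery by the detectors.
   Burst durations are ≈1 s — the perturbation delivers erroneous feedback
   for 2 s, so a sustained low-frequency response is the plausible regime,
   and it is also what makes the asynchronous labelling (below) coherent.
   `snr_scale` multiplies all injected amplitudes; 0 disables injection and
   is the null condition used throughout the calibration tests.
3. **Ocular artifacts.** Blinks (Gaussian bumps, ≈100 µV, ~15/min) and
   smoothed step-like saccades on the EOG channels leak into the EEG with
   frontal-dominant gains (up to ≈0.25 at Fpz), giving the EOG regression
   something real to remove.
4. **Thumbstick.** A smoothed random walk in [−1, 1]²; during a
   perturbation a corrective deflection toward the perturbation angle is
   added, so the confound analysis (classifying on the stick trace alone)
   faces weakly informative, realistic structure.

By default severity changes **only the event label**, never the injected
waveform — the null the severity analysis should recover. Setting
`severity_scales` breaks this deliberately to verify the contrast machinery
can detect a severity effect when one exists.

What the generator does *not* emulate: volume-conduction from a head model,
non-stationarity over the session (drowsiness, impedance drift), alpha
rhythms and other narrowband idle oscillations, muscle artifact, and
single-trial latency jitter of the ErrP components. Passing recovery tests
on this generator therefore demonstrates that the analysis machinery is
correct and leak-free, not that real-EEG accuracies would reach the same
values; the bundled reference tables show what a real ten-subject study of
this design achieved.

## Preprocessing

The conditioning chain is band-pass → EOG regression → common average →
segmentation, recorded in a provenance flag on the recording.

* **Filtering**: 4th-order Butterworth 0.5–60 Hz plus a 2nd-order band-stop
  at 48–52 Hz. Offline stages use zero-phase forward-backward application;
  the deployment path of the asynchronous detector can request causal
  filtering (`causal = TRUE`) since a real-time system cannot look ahead.
* **EOG regression**: ordinary least squares of every EEG channel on the
  three EOG channels, coefficients `solve(cov(EOG), cov(EOG, EEG))`,
  fitted on the full band-passed recording (no separate calibration
  segment is simulated; the choice is logged in provenance). A ridge
  term is added with a warning if the EOG covariance is near-singular.
  EOG channels are corrected out of the EEG but kept unmodified, because
  the confound analysis later classifies on them.
* **Common average reference**: per-sample mean over EEG channels only.
* **Trials**: 1-s epochs, half-open windows. Error trials lock to onsets;
  `noError` candidates tile the recording on a 1-s grid and survive only if
  the window plus a 1-s guard on each side contains no event activity,
  where an execution error is "active" for its entire 2-s perturbation.
  This is the strict reading of "no error during or adjacent to the trial"
  and removes the label noise that onset-only exclusion would leave.

Throughout the package, time is in seconds, sample indices are 0-based and
windows are half-open `[t0, t1)`: sample *i* covers time *i*/fs. This
single convention fixes every off-by-one question; e.g. the 0.2–0.9 s
feature range at 512 Hz is exactly 358 samples per channel.

## Spectral estimation

Two estimators serve different stages:

* **Welch** (`welch_psd`): Hann-tapered averaged periodograms, segment 256,
  overlap 128, FFT length 512 — at 512 Hz this yields 1-Hz bins, so "the
  first 40 bins" of the event-locked frequency features span 0–39 Hz, inside
  the filter pass-band. One-sided density scaling makes the spectrum
  integrate to the signal variance, which the tests verify (Parseval).
* **Burg** (`burg_psd`): maximum-entropy AR estimation, order 16 by
  default, evaluated on 1–12 Hz at 1-Hz steps. The recursion (minimizing
  summed forward+backward prediction error) is implemented in C++ because
  the chronological cross-validation evaluates it roughly half a million
  times per session (windows × channels); `stats::ar.burg` serves as an
  independent oracle in the tests, never as the implementation. Constant
  segments return an epsilon-flat spectrum rather than failing, so an
  all-zero window cannot crash a detector.

Feature scoring uses the squared point-biserial correlation (`r2_scores`),
with zero-variance features scoring 0 and top-*k* selection breaking ties
by lower index so that selection is deterministic. Power features enter the
classifier untransformed: a log transform was evaluated during design and
did not improve separability on this generator.

## Event-locked classification

Features are raw samples (time), leading Welch bins (frequency), or their
concatenation, from the 0.2–0.9 s post-event range, over a configurable
channel subset (EEG by default; EOG-only and stick-only runs implement the
confound controls). The classifier is a linear soft-margin SVM (libsvm,
`C = 1`) preceded by per-feature z-scoring — necessary because time-domain
microvolts and spectral densities live on different scales — with the
scaling statistics estimated strictly on training data.

Cross-validation is stratified 10-fold; the training fold is balanced by
down-sampling the majority class before fitting. Balancing is pure
subsampling and fits no statistics, so it cannot leak; doing it inside the
fold (rather than once globally) keeps every held-out trial evaluable. A
dedicated test spikes a held-out trial with an extreme outlier and verifies
the remaining trials of that fold classify identically — the standard
smoke test for standardization leakage.

Significance uses a label-permutation test: each repetition permutes the
label vector once and re-runs the entire cross-validation; the threshold is
the empirical 95th percentile of permuted accuracies. The reference design
uses 1200 repetitions; the bundled analyses and acceptance checks use 200,
which stabilizes the 0.95 quantile to well within the width of the band it
is compared against. Note that pooled k-fold accuracies are correlated
across folds, so the null spread is wider than the binomial
`sqrt(0.25/n)`; wherever the tests need a chance band they therefore derive
it from the permutation distribution itself (a Monte-Carlo band) rather
than from the binomial formula.

Severity contrasts classify execution trials of one perturbation angle
against another for all 10 pairs plus the joined mirror-angle contrast
(45°+315° vs 90°+270°); under the generator's default
severity-independent injection all of these must sit inside the chance
band, and a sensitivity configuration (`severity_scales`) verifies the
machinery detects a true severity effect.

## Asynchronous detection

A 1-s window slides over the whole preprocessed signal in 62.5-ms steps (32
samples — the step must be sample-aligned). Each window is summarized by
Burg spectra of its 0.1–0.5 s sub-window on every EEG channel (12 × 28
features): the short sub-window trades spectral resolution for reaction
time, the reason the reference design found it optimal asynchronously.
Training uses event-locked trials: r² feature selection keeps the 20
strongest features, a linear SVM is fitted — with the error-class cost
weighted 5:1 for outcome detectors, whose positive class is far rarer,
while execution detectors balance by subsampling — and a Platt sigmoid
`p = 1/(1 + exp(A·d + B))` maps decision values to probabilities. The
sigmoid is fitted by regularized maximum likelihood on decision values
obtained from 3-fold internal cross-fitting, because calibrating on
resubstitution decision values yields overconfident sigmoids. The final
statistic is a weighted average of the last three probabilities, default
weights (1, 2, 3)/6 favouring the newest step (the reference design says
only "weighted average"; the weights are configurable and the first two
steps renormalize over available history), thresholded at 0.8 by default.

Evaluation is chronological 10-fold cross-validation: the recording is cut
into 10 contiguous equal segments; each fold trains on event-locked trials
that are *temporally disjoint* from the held-out segment and slides the
detector over that segment only, excluding windows that straddle segment
boundaries. A window's ground-truth label is positive when its start lies
within 0.5 s after an onset of the target kind, so the feature sub-window
overlaps the injected response. Windows just outside that range partially
overlap the response too; they are scored as negatives (all non-boundary
windows are scored), which is the honest, slightly pessimistic convention.

## Metrics

* **ROC/AUC** (`roc_auc`): sensitivity/specificity swept over thresholds
  0–1 in 0.01 steps, curve anchored at (0,0) and (1,1), trapezoid area.
  This agrees with the Mann–Whitney rank statistic to within threshold
  quantization (< 0.01), which both the unit tests and the acceptance
  script verify on random traces.
* **PSR/NSR** (`psr_nsr`): the timeline is cut into 1-s bins anchored at
  t = 0 (the bin phase is unspecified in the reference design; anchoring at
  the recording start is the only canonical choice). A bin is positive if
  any error's label interval intersects it; PSR_θ is the percentage of
  positive bins containing at least one above-threshold decision, NSR_θ
  the percentage of negative bins containing none. PSR is antitone and NSR
  monotone in θ, which is tested.
* **Difference waveforms** (`erp_difference_stats`): pointwise Welch-type
  unequal-variance two-sample t-tests across trials at one channel,
  Bonferroni-corrected over the number of time samples tested (the test is
  unnamed in the reference design; the unequal-variance form is the safe
  default for unequal trial counts). Contiguous significant samples merge
  into intervals with their peak latencies. These statistics are computed
  across trials within one session; the reference figures pooled across
  subjects, which a single synthetic session cannot reproduce.
* **Aggregation** (`aggregate_report`): arithmetic means across
  subject-level rows, mirroring how multi-subject tables report their
  "Mean" row; the bundled ten-subject reference tables reproduce their
  printed group means to table precision.

## Problem sizes and numerical choices

The bundled analyses and checks run on deliberately scaled sessions chosen
as the package's own desk scale: a 20-minute session for recovery runs
(≈140 execution, ≈25 outcome events), a 15-minute null session for
calibration, a 40-minute session for severity contrasts (≈55 trials per
angle), and 200 permutations for significance thresholds. A full-hour
session with the reference repetition counts runs identically, only longer.
Fixed seeds flow from a single integer through a deterministic splitter, so
every stage is bit-reproducible; the generator records its seed in the
recording metadata.

Degenerate inputs are handled explicitly: empty event tables epoch to empty
trial sets; events whose window does not fit are dropped with a message;
near-singular EOG covariances trigger a ridge solve with a warning;
constant segments yield epsilon spectra; zero-variance features score
r² = 0; feature selection with fewer than 20 candidates keeps all with a
warning; folds without an error event are evaluated for specificity only.

## Known limitations

* The generator's stationary background and jitter-free templates make
  recovery easier than real EEG; absolute synthetic accuracies should not
  be read as forecasts for real recordings.
* The EDF codec is minimal (16-bit, one-second records, single sampling
  rate) — sufficient for round-tripping this pipeline's sessions and
  readable by standard tools, but not a general EDF+ implementation.
* The asynchronous path is evaluated offline; the causal-filtering flag
  honours real-time constraints for the filters, but no streaming runtime
  is provided.
* Severity is encoded in the thumbstick confound but not, by default, in
  the EEG — matching the reference finding; the generator cannot tell us
  whether real severity effects exist below that study's sensitivity.
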