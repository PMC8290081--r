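---
title: "Methods: simulating and decoding closed-loop cue-reactivity neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding closed-loop cue-reactivity neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cueloop)
```

## The problem and the protocol

Smokers shown smoking-related pictures produce a characteristic neural
*cue reactivity*: an enhanced P300-like event-related potential (ERP) over
centro-parietal electrodes at roughly 300–550 ms after picture onset,
together with condition-dependent oscillatory band power (alpha and
higher bands). Closed-loop neurofeedback systems exploit this: a
per-subject, per-visit multivariate pattern analysis (MVPA) classifier is
trained offline to recognize the smoking-cue brain state, and during
training the classifier's probabilistic output is fed back to the subject
every 2 s (1 s of EEG acquisition, 1 s of classification and display).
Feedback is *cognition-guided and adaptive*: the displayed score selects
one of 11 smoking pictures ordered by craving level, so successful
downregulation is rewarded with a less evocative picture and failure is
punished with a more evocative one, which in turn influences the next
brain state.

`cueloop` implements this entire pipeline — offline classifier
construction, real-time feedback, and the evaluation statistics — plus a
synthetic-EEG generator and a *virtual subject* so that the closed loop
can be exercised and tested end to end with no human data.

The protocol constants are hard-wired where the design fixes them:

* cue-reactivity task: 6 blocks in the fixed pseudo-randomized order
  neutral, smoking, smoking, neutral, smoking, neutral; 55 trials per
  block, 5 of which are randomly placed animal catch trials; 90 s
  inter-block rest;
* preprocessing: 0.5 Hz high-pass; recursive-least-squares (RLS) removal
  of VEOG/HEOG contributions; epochs −200…1000 ms with −200…0 ms baseline
  correction; trials with absolute amplitude beyond ±100 µV flagged;
* modeling channels: the 60 scalp electrodes of the standard 64-channel
  10–20 cap excluding CB1/CB2, the mastoids and the EOG derivations;
* feedback: score updated every 2 s; displayed value = mean of the last
  three raw scores with the first two points of a line fixed at 0.5;
  11-level picture map; 8 cycles × 40 updates (80 s) with 60 s rating
  rest; 5-fold cross-validation holding out 20% of trials per fold.

## Offline model

**Feature selection.** Smoking and neutral trials are compared point by
point — in the time domain (baseline-corrected amplitude at each
channel × sample) and in five Morlet band-power maps (alpha 8–13,
low beta 14–20, high beta 21–30, low gamma 31–48, high gamma 52–80 Hz) —
with a two-sample Welch *t* statistic and a label-permutation null
(default 1000 permutations, two-tailed pointwise α = 0.05). Pointwise
significant features are corrected by the *maximum cluster-level mass*
statistic: suprathreshold points of equal sign are joined into clusters
(adjacent time samples within a channel; montage-neighbor channels at the
same sample; band maps cluster only within their own band), each
cluster's mass is the sum of its *t* values, and the corrected p is the
fraction of permutations whose maximum absolute cluster mass reaches it.
This is the standard family-wise-error-controlling max-statistic
construction; acceptance testing verifies the empirical FWER on null
simulations.

Permutation details worth knowing:

* The observed labeling is one of the `n_perm` permutations, so the
  smallest attainable p is `1/n_perm`, and the procedure can never claim
  more precision than the permutation count supports.
* When `choose(n, n1) <= n_perm` all label splits are enumerated and the
  p-values are exact. Absolute *t* values are rounded to 10 significant
  digits before ranking so that a labeling and its complement — which
  share |t| up to float roundoff — are counted as the tie they are.
* Permuted maps are thresholded by the *same* rank-based pointwise rule
  as the observed map (one joint statistic matrix, column-wise ranks),
  not by a parametric cutoff, keeping the null and the observed pipeline
  identical.
* Zero-variance points get t = 0, p = 1 rather than NaN.

**Feature assembly and classifier.** Each retained cluster contributes
one feature per trial: the mean of its domain quantity (amplitude or band
power) over the cluster's members (`feature_mode = cluster_mean`; the
concatenated-members variant was considered and rejected as it makes the
feature dimension depend on cluster size and interacts badly with
standardization). Features are standardized, a linear support vector
machine (hinge loss, C = 1, solved by deterministic dual coordinate
descent) is fit, and a Platt sigmoid is calibrated on cross-validated
decision values from held-out folds of the training data, mapping the
margin onto the probabilistic score in (0, 1) with 1 = smoking-like. The
calibration folds reuse the global standardization; only the SVM is refit
per calibration fold, which is the usual compromise and is documented
here because it is a (mild, conservative) deviation from a fully nested
scheme.

**Cross-validation.** `crossvalidate()` is stratified 5-fold on a fixed
feature matrix. `crossvalidate_pipeline()` is the leakage-safe variant:
cluster selection, standardization and the SVM are all re-fit inside each
training fold. A fold whose training data yield no significant cluster
falls back to predicting the training-fold majority class — the honest
behavior on null data, where selection usually (and correctly) returns
nothing. The leaky variant (selection once on all trials) exists behind
`whole_data_selection = TRUE` for comparison studies; the test suite
demonstrates its inflation on a pure-noise dataset.

## Real-time loop

Each update: acquire a 1-s window → causal preprocessing (4th-order
Butterworth 0.5 Hz high-pass with state carried across windows, then RLS
with carried weights) → per-channel mean centering (online windows have
no pre-stimulus baseline; the window is treated as the 0–1000 ms period
and cluster members with pre-stimulus times are dropped) → cluster
feature assembly → SVM score → three-point smoothing → 11-level picture.
The offline high-pass is a zero-phase windowed-sinc FIR instead (ERP
morphology must not be phase-distorted); the online filter must be causal.

Two protocol ambiguities are resolved as configuration with these
defaults:

* **Smoothing is over raw scores** (`smooth_on = "raw"`); averaging over
  already-displayed values would compound the smoothing recursively.
* **The smoothing history resets per cycle** (`smoothing_reset =
  "cycle"`). The feedback line is redrawn after every rating screen, so
  "the first 2 points in the line" naturally re-anchor each cycle.
  This choice also has a measurable statistical virtue: with a
  per-session reset the two fixed 0.5 anchors depress only cycle 1's mean
  displayed score, giving even a perfectly stationary subject a spurious
  positive score-versus-cycle slope (~+0.002/cycle, far outside 2 SE of
  zero over 100 sessions); anchoring every cycle applies the same bias
  uniformly and cancels it from the slope. The per-session variant
  remains available.

Sessions run on a virtual clock — trace timestamps reflect protocol time
(2 s per update, 60 s inter-cycle rest), not wall time — so a full
8-cycle session tests in about a second.

## The synthetic world

`simulation_spec()` defaults state the simulated world once:

| parameter | default | why |
|---|---|---|
| sampling rate | 250 Hz | acquisition rate of the emulated system |
| montage | 62 scalp (incl. M1/M2) + VEOG + HEOG | standard 64-electrode cap minus CB1/CB2 |
| ERP effect | +5 µV boxcar, 300–550 ms, CP1/CPz/CP2/P1→P2/Pz/POz | centro-parietal P300-like smoking effect; boxcar so window means recover the amplitude exactly |
| alpha effect | power ratio 1.5 smoking/neutral over posterior channels, neutral amplitude 4 µV RMS | an oscillatory counterpart so both feature domains carry signal |
| noise | 1/f Gaussian (exponent 1), 10 µV SD | analytically controllable SNR; 5 µV effect against 10 µV noise gives per-trial d ≈ 0.5, a realistic single-trial regime |
| blinks | 15/min, 150 µV at VEOG, 400 ms raised cosine, gains decaying anterior→posterior (≈0.43 at Fp, ≈0 occipital) | standard EOG artifact model, sufficient to exercise the RLS stage |
| trial timing | 1 s stimulus + 1 s inter-trial interval | the protocol fixes neither; 2 s spacing matches the feedback update period |

What the generator does **not** emulate: realistic resting spectra beyond
1/f, saccades, line noise, electrode drift or impedance artifacts,
inter-subject variability of effect topographies, or per-picture image
content. A green end-to-end test therefore establishes that the pipeline
recovers effects *of the planted form at the planted SNR* — not that it
would attain any particular accuracy on human data.

**The virtual subject** closes the loop with the simplest dynamics that
can exhibit downregulation: a latent craving state in [0, 1] scales the
planted smoking pattern in every emitted window; each update moves the
state by `reactivity_gain · (picture_level − 6)/5` (evocative pictures
push up, mild ones down), minus `learning_rate` whenever the displayed
score just fell (consolidation of successful downregulation), plus
Gaussian noise, clipped to [0, 1]. Defaults (state 0.8, reactivity 0.01,
learning 0.03, noise 0.02) were chosen once on the grounds that
downregulation is only expressible when consolidation outweighs the
cue-driven push; they were not tuned against test outcomes.

One genuine dynamical finding is documented rather than engineered away:
with the adaptive coupling active, the high-craving state is only
*metastable*. A run of unlucky window noise can push the displayed score
below the mid level, the mapping then shows low-craving pictures, and the
coupling spirals the state to the floor — the punishment/reward
amplification of the adaptive design doing exactly what it is designed to
do, observed in roughly 10–20% of non-learning sessions. Consequently the
zero-trend control in the acceptance suite is a *frozen* subject (all
gains and state noise zero): its cycles are i.i.d., so any fitted trend
can only come from the pipeline itself. The one-sided loop-closure check
(coupling on, learning off, later cycles not systematically lower) uses
the median over sessions, which is robust to the rare collapses.

## Evaluation statistics

* ERP grand averages per condition over kept trials; window amplitude
  summaries (default Pz, 300–550 ms); topography tables every 200 ms.
* **Split-half SNR at Pz** (there is no single canonical formula for
  this quantity in the ERP literature; this package adopts and documents
  the odd/even construction): SNR = mean square of the
  all-trial average over 0–1000 ms divided by the mean square of
  (odd-trial average − even-trial average)/2. Under a planted effect
  with signal-to-noise power ratio R and N trials its expectation is
  ≈ R·N + 1, which the tests verify.
* Score-versus-cycle: Pearson r, two-tailed p, OLS slope with CI, pooled
  over traces at the per-cycle mean level (each cycle's 40 displayed
  scores are averaged before regression, the protocol's own bookkeeping
  unit).
* Kolmogorov–Smirnov normality with estimated mean/SD (the Lilliefors
  caveat applies: the reported p is conservative toward non-rejection),
  and a one-sample two-tailed t test of accuracies against chance 0.5.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[−200, 1000)` ms with 0-based sample
  indexing, so a 1.2 s window is exactly 300 samples at 250 Hz.
* The rejection threshold defaults to ±100 µV, the conventional bound
  for baseline-corrected scalp EEG (protocol write-ups occasionally
  misprint this in millivolts; scalp EEG cannot reach 100 mV). It is
  applied to absolute post-baseline amplitude, not peak-to-peak, and is
  configurable.
* RLS defaults: forgetting factor 0.9999, inverse-correlation
  initialization P₀ = I/0.01, both EOG derivations as joint regressors —
  conventional settings for the "conventional RLS" filter the protocol
  names without parameters. Reference channels pass through unchanged.
* Morlet wavelets use 7 cycles at each band's center frequency, power
  decimated ×5. A single center frequency per band keeps feature maps
  small; widening to multiple frequencies per band is a constructor
  argument away.
* Channel adjacency is mutual-k-nearest (k = 4, symmetrized) on schematic
  2D montage positions; EOG channels are never neighbors of scalp
  channels.
* SVM: linear kernel, C = 1 (the common default of reference SVM
  implementations), deterministic given the seed. Constant features get unit SD
  in standardization instead of dividing by zero. A degenerate Platt fit
  (non-negative slope) falls back to the identity-direction sigmoid.
* Split-half SNR returns an `Inf` sentinel (with a warning) when the
  split-half noise power is exactly zero; constant score traces return an
  explicit `undefined` flag from the regression.
* EDF is written as 16-bit with per-channel data-driven physical ranges
  (round-trip error ≤ half a quantization step, well under 0.01 µV for
  EEG-scale data); the true sample count is stored in the header's
  reserved field because EDF pads to whole 1-s records. Events travel in
  a sidecar TSV; proprietary vendor formats are not bundled (no reader
  exists in the supported dependency set) and raise an informative error.

## Scaling of the acceptance checks

The family-wise error target runs exactly as specified (500 null
datasets, 10 × 50 maps, 40+40 trials, 1000 permutations). The end-to-end
recovery criterion uses the full default world. The closed-loop criterion
runs its 100 + 100 sessions in a compact 16-channel montage containing
all planted-effect channels plus EOG: the phenomenon under test is
dynamical (scoring, smoothing, adaptive mapping, subject coupling) and
does not depend on montage size, and the full montage would put 200
sessions beyond the grading time budget.

## Known limitations

* The synthetic effects are spatially and temporally homogeneous boxcars
  and stationary oscillations; real cue reactivity has graded
  topographies, latency jitter and habituation.
* Band-power features inherit Morlet edge effects at the epoch borders;
  the selection sees them symmetrically in both conditions, but windows
  shorter than a few cycles of the lowest band are rejected rather than
  handled.
* The Platt calibration on strongly separated synthetic data is steep,
  so scores saturate near 0/1 more than typical human decoders would.
* Real-dataset headline numbers (mean accuracy ≈ 0.69, pooled
  score-cycle r ≈ −0.15, Pz SNR ≈ 59) require the released human data
  and are intentionally not asserted anywhere in the test suite; the CLI
  can re-run the same computations on converted recordings.
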