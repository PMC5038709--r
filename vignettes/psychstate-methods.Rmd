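---
title: "Methods: HMM-based psychiatric state prediction from biosensor signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HMM-based psychiatric state prediction from biosensor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psychstate)
```

## The model

`psychstate` treats the psychiatric state of a monitored subject as a
latent first-order Markov chain over three states of increasing
clinical severity — Normal (N), Atypical (A), Emergency (E) — observed
indirectly through wearable biosensors and psychometric instruments.
The severity grading follows the suicidality item (item 3) of the
Hamilton Rating Scale for Depression: a score of 0 maps to N, 1–2 to A,
and 3–4 to E. Because that item *defines* the state label, it is
deliberately excluded from the observation features; including it would
leak the label into the model.

Observations are collected once per slot of duration τ (default 15 s)
and predictions are issued per window of w slots (default w = 60, a
15-minute window matching the interval at which a consulting
psychiatrist re-assesses a patient). The model is a hidden Markov model
λ = {π, T′, E′} with discrete emissions over a K-symbol codebook
(default K = 16) obtained by k-means quantization of the discriminant
feature scores. A per-state diagonal-Gaussian emission model is
available behind the same interface, but the discrete codebook is the
default because path-counting training is defined over countable
emissions.

Two training algorithms are provided:

* **Viterbi path counting (VPC)** — a single pass over the data that
  counts initial states, transitions and emissions along each
  sequence's path and normalizes with a Laplace pseudo-count (default
  1). With psychiatrist labels available the counts are taken along
  the labeled paths (supervised, the default); without labels the
  model starts from a uniform λ with 1 % Dirichlet jitter, computes
  each sequence's Viterbi path once, and counts along those decoded
  paths. Both modes are implemented because the clinical workflow the
  package models provides per-slot expert remarks, but the training
  description itself does not fix the mode.
* **Stochastic variational inference (SVI)** — Dirichlet variational
  posteriors over every probability row, updated by noisy natural
  gradients: sample a mini-batch (default 11 sequences), run
  forward–backward under the posterior geometric means, scale the
  expected counts to the full dataset, and blend natural parameters
  with step size ρ_i = 0.9 · i^(−κ). The initial rate 0.9 and batch 11
  are the published operating point; the forgetting rate κ = 0.6 is
  this package's choice from the standard stable range (0.5, 1]. The
  per-iteration cost depends on the batch, not the dataset, which is
  the algorithm's scalability argument; with batch = full data and
  unit step the update degenerates to batch variational inference,
  which the tests assert exactly.

### Decoding and the prediction ensemble

The most likely state sequence Q of a window is computed by max-product
dynamic programming (Viterbi) in log space with backpointers.
A literal per-step argmax reading of the prediction recurrence — each
state chosen given only the previously chosen state, with no
backtracking — is also implemented as `greedy_decode()`, because the
recurrence as usually written is exactly that greedy rule while the
surrounding description invokes the Viterbi algorithm. The two
decoders provably differ on adversarial models (a test measures the
discrepancy rate on random instances); `viterbi_decode()` is the
package default and the discrepancy is surfaced rather than silently
resolved.

From the decoded window Q three candidates are extracted: the state
with the longest consecutive run (LRL), the state with the highest
frequency count (HFC), and the most recent state (MRS). Majority
voting over the ensemble (LRL, HFC, MRS) gives the window prediction.
Tie-breaks are deliberate design choices:

* LRL ties go to the most recent tied run (recency mirrors MRS);
* HFC ties and 1-1-1 voting ties go to the more severe state
  (E > A > N) — clinically conservative, preferring to flag an
  emergency;
* Viterbi argmax ties go to the earlier state in severity order
  (N < A < E), making decoding deterministic.

The frequency-count relaxation procedure referenced alongside the
ensemble algorithm is implemented as exactly the per-state occurrence
count over Q that its prose describes; its printed body is not
available.

## The synthetic cohort generator

No clinical recordings are distributed with the package (the study
cohort it emulates — 55 subjects: 14 Emergency, 16 Atypical, 25 Normal —
is not deposited anywhere), so the generator is a first-class module
that produces labeled subjects with the statistical structure the
method assumes:

* **State trajectories.** Each subject has a dominant state and a
  sticky transition matrix biased toward it (self-stay 0.85,
  return-to-dominant 0.55); trajectories are resampled (bounded
  attempts) until at least 60 % of slots are in the dominant state, so
  a subject "categorized as emergency" still shows within-subject
  dynamics.
* **ECG** — a sum-of-five-Gaussians P-QRS-T template repeated at a
  state-dependent heart rate (65/75/90 bpm for N/A/E) with
  state-dependent R-R jitter (50/40/25 ms; heart-rate variability
  falls with arousal) plus white noise. Template fiducials are
  analytically known, so every extracted interval can be checked by
  parameter recovery.
* **EDA** — a state-dependent tonic level (2.0/3.0/4.5 µS) with slow
  sinusoidal drift and Poisson-arriving skin conductance responses
  (2/4/8 events·min⁻¹) with rapid-rise/exponential-decay shape.
* **BVP** — a two-Gaussian pulse (systolic peak M, diastolic peak Q,
  dicrotic notch between) locked to the subject's ECG beat times with
  a 0.2 s transit delay; systolic amplitude and the
  diastolic:systolic ratio are state-dependent (vasoconstriction under
  arousal).
* **EMG** — 20–450 Hz band-limited Gaussian noise whose envelope
  alternates active tone (0.05/0.08/0.12 mV) and rest gaps
  (8/4/1 gaps·min⁻¹; psychological tension suppresses EMG gaps).
* **Scale scores** — one draw per subject (questionnaires are answered
  at most weekly) from rounded truncated normals with state-dependent
  means, clamped to each instrument's published range; HRSD item 3 is
  drawn from the state mapping itself. History flags are Bernoulli
  with state-dependent rates.

Sampling rates (ECG 250 Hz, BVP 64 Hz, EDA 16 Hz, EMG 1 kHz) are
typical wearable values; the emulated study does not state them. The
default recording length is one observation window (15 min) per
subject: the emulated consultations ran 45–135 min, but one window per
subject keeps the default evaluation at 55 window-level predictions —
the same prediction count as the published confusion table — and keeps
the full study tractable on one CPU. All effect sizes above were fixed
once as field-typical values before any evaluation and are
configurable; an `effect_scale` knob shrinks or amplifies every
between-state separation jointly so that the monotone relationship
between configured separation and downstream accuracy can be tested.

**What passing tests do and do not show.** The generator produces
feature-level realism (recoverable fiducials, plausible rates and
amplitudes, Markov state dynamics), not physiological realism: ECG
morphology is a fixed template, channels are conditionally independent
given the state, there are no artifacts, electrode drift, missing
segments or inter-subject morphology differences, and scale scores are
conditionally Gaussian. Accuracy obtained on synthetic cohorts
therefore validates the *pipeline* — that the implementation extracts,
selects, trains and decodes correctly when the modeled structure is
present — and does not estimate clinical performance.

## Feature extraction choices

Band edges (zero-phase Butterworth, order 6): ECG 0.5–40 Hz,
BVP 0.5–8 Hz, EDA low-pass 1 Hz, EMG 20–450 Hz — conventional clinical
bands; order 6 was chosen as the highest order numerically stable
across all four band configurations under forward–backward filtering
while attenuating a tone 25 % past the edge to under 5 % RMS. Signals
are mean-centered before filtering to suppress start/end transients.
The moving average is trailing with edge truncation (the window for the
first samples is whatever is available), i.e. causal and
streaming-friendly. Filtering and extraction are strictly slot-local:
samples outside a slot cannot influence its feature vector (asserted by
test).

* R peaks: derivative-squared energy over a 150 ms window, adaptive
  threshold, 200 ms refractory period. QTc uses Bazett's formula
  QT/√RR; "first/second derivative" features are means of the
  successive-difference series of the per-beat measurements.
* SCRs: detected by their rise rate (≥ 0.02 µS/s sustained ≥ 0.2 s,
  an order of magnitude above tonic drift), measured trough-to-peak,
  kept at ≥ 0.05 µS amplitude with ≥ 1 s separation — standard
  electrodermal conventions.
* BVP: systolic peaks above 60 % of the segment range with 0.4 s
  refractory; the diastolic peak must be an interior local maximum
  after the dicrotic notch — beats without one leave the Q-dependent
  features flagged missing. The stiffness index uses a nominal height
  constant of 1.75 m because subject height is not part of the data
  model (a documented limitation). Both the M-M interval and the
  foot-to-foot pulse interval are computed although they are nearly
  redundant.
* EMG gaps: 100 ms RMS envelope below 10 % of slot RMS for ≥ 200 ms.
* Missing values are always explicit `NA`s ("flagged missing"), never
  silent zeros; the pipeline imputes them with training-set medians
  before normalization.

## Pipeline numerics

Mutual information uses equal-width binning with 10 bins on the
min-max-normalized `[0, 1]` scale — the simplest estimator whose zero
set is what the selection rule needs. mRMR uses the difference (MID)
criterion with ties broken by feature name for reproducibility. PCA
keeps the components covering 95 % of variance and fixes each
component's sign so its largest-magnitude loading is positive
(reproducible across BLAS libraries). The kernel discriminant step is
a Baudat-style kernel Fisher discriminant: RBF kernel with the median
pairwise distance as bandwidth, within-class scatter regularized by
ε = 1e−6 (raising ε is the prescribed fix if the scatter is singular),
generalized eigenproblem solved by Cholesky whitening. For large
training sets the eigenproblem is solved on at most 750 stratified
landmark rows and all data are projected through the landmarks, keeping
the O(n³) scatter algebra bounded; the exactness tests run below the
cap. With a linear kernel and small ε the directions coincide with
classical LDA, which the tests verify against the closed form.
Constant columns min-max-normalize to 0 (avoiding 0/0), and
out-of-sample values are clipped to `[0, 1]`.

Log-space decoding uses an additive floor of −1e9 for zero
probabilities so that windows containing an observation impossible
under every state still decode (and are flagged) instead of
underflowing.

## Evaluation

Confusion counts are one-vs-rest per class. Rates with zero
denominators are flagged `NA`, never reported as 0 or 1. The
diagnostic odds ratio uses the printed formula (TP·TN)/(FP·FN) with the
Haldane 0.5 continuity correction (flagged) when a cell is zero; its
95 % interval is the standard log-normal
exp(ln DOR ± 1.96·√(1/TP+1/FP+1/TN+1/FN)). The published table this
mirrors prints interval columns that are inconsistent with any standard
DOR interval formula, so those printed intervals are not reproduced or
asserted anywhere. AUC is the Mann–Whitney rank statistic, one class
versus the rest; since majority voting yields no continuous score, the
per-window score is defined as the class's vote share scaled by the
per-slot geometric-mean path probability, a monotone confidence proxy.

Cross-validation is stratified at the *subject* level by dominant
label (never at the slot level), so no subject contributes to both
training and test; a configuration in which a training fold would lose
a class entirely raises an error suggesting a smaller k.
Leave-one-subject-out (k = number of subjects) runs as the degenerate
case. The sensor ablation ladder (history flags only, then +EDA, +ECG,
+BVP, +EMG) mirrors the incremental test settings of the emulated
study; the package asserts the monotone ordering — each added sensor
never lowers pooled sensitivity + specificity — rather than any printed
values, which belong to the unavailable clinical cohort.

## Problem sizes used in the shipped studies

The default evaluation study runs on the default 55-subject cohort
(one 60-slot window each, 3 300 slots) with 5-fold cross-validation
and the five ablation masks. Unit and property tests use 9–12 subject
cohorts with 10 s slots and 12-slot windows, reduced sampling rates
(ECG 200 Hz, EMG 400 Hz), parameter-recovery simulations of 200
length-100 sequences, and exhaustive decoding oracles at 3⁶ paths —
sizes chosen so the full suite exercises every code path in minutes on
a single CPU while keeping estimator errors well inside the asserted
tolerances.

## Known limitations

* Feature-level synthetic realism only; no artifact or morphology
  diversity (see above).
* The discrete-codebook emission model loses within-symbol geometry;
  K = 16 was fixed a priori and not tuned.
* The stiffness index is a scaled reciprocal of the M-Q delay, not a
  true height-calibrated index.
* SVI is implemented for discrete emissions only.
* The greedy/Viterbi discrepancy is reported, not resolved; downstream
  results use Viterbi.
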