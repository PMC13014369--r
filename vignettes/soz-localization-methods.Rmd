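---
title: "Localizing the seizure onset zone from ictal band power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the seizure onset zone from ictal band power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sozpower)
```

## The problem

In drug-resistant focal epilepsy, surgery succeeds when the resected
tissue contains the seizure onset zone (SOZ) — the electrodes where
ictal activity first appears. Clinicians label the SOZ by visual review
of intracranial EEG (iEEG), a slow and partly subjective process.
`sozpower` formalizes a quantitative alternative: spectral power in the
first 20 s after seizure onset differs systematically between SOZ and
non-SOZ electrodes across several frequency bands, and those differences
can be combined by an ensemble classifier both to flag SOZ electrodes
and to predict whether resecting the labelled tissue will leave the
patient seizure-free.

## Preprocessing

The chain is fixed in this order: artifact-channel exclusion → notch →
common average reference (CAR) → epoching.

* **Artifact channels** are excluded by a caller-supplied label list;
  identification is visual in practice and out of scope here. Excluding
  before CAR matters: a contaminated channel would otherwise leak into
  the reference of every other channel.
* **Notch** is an order-2 Butterworth band-stop (default bandwidth 2 Hz)
  applied forward–backward (zero phase) at the mains frequency and up to
  its third harmonic. Zero-phase filtering is essential because epoching
  is aligned to a clinically marked onset time; a causal filter would
  shift it. No particular filter family is canonical for this step; the
  Butterworth band-stop was chosen for its flat passband (within ±1 dB)
  and ≥ 20 dB attenuation at the notch centre.
* **CAR** subtracts the instantaneous across-channel mean. It is
  idempotent, and the output's across-channel mean is zero at every
  sample to floating tolerance.
* **Epoching** cuts the *ictal* window [onset, onset + 20 s) and the
  *baseline* window [onset − 30 s, onset − 20 s). The time-to-sample map
  is `floor(t * fs)` with half-open intervals, so the ictal epoch is
  exactly 20·fs samples (±1 at most). Onsets need ≥ 30 s of pre-onset
  and ≥ 20 s of post-onset data; anything less is rejected with the
  required margin in the message. Baseline power is computed and carried
  along but enters no downstream model by default; it is used by the
  test suite to verify that injected onset patterns energize their
  declared bands.

## Multitaper band power

Power spectral density is estimated per channel in 2.5 s windows
advanced by 0.5 s, each window tapered with K = 5 discrete prolate
spheroidal sequences (DPSS) at time–bandwidth NW = 3 and averaged across
tapers without eigenvalue weighting. The tapers are computed from the
standard symmetric tridiagonal eigenproblem, normalized to unit energy;
the test suite checks the whole estimator against an independent
dense-matrix DPSS + explicit-DFT implementation to 1e−8 relative error.
NW = 3 / K = 5 are the common defaults for windows of this length — a
±1.2 Hz analysis half-bandwidth — and are exposed in `spectral_config()`
rather than hard-coded.

Scaling is one-sided density (μV²/Hz): integrating the PSD over
frequency recovers the windowed signal variance (Parseval), which the
suite verifies within 30% on white noise and 15% for a pure sinusoid's
A²/2. Windows start at the epoch start and no padding is used, giving
`floor((T − 2.5)/0.5) + 1` windows: 36 for the 20 s ictal epoch, 16 for
the 10 s baseline.

Band power is the *mean* PSD over the bins in each of the six canonical
bands — delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–90,
high gamma 90–150 Hz — as half-open intervals `[lo, hi)` so shared edges
are counted once. Mean (not integrated) band power keeps values
comparable across bands of different widths.

## Group statistics

For each seizure, electrodes are grouped by the clinician SOZ label and
the group-mean power series (± SEM) is summarized by its trapezoidal
area under the curve (AUC) over the 36 ictal windows — one AUC per band,
group and seizure. AUC distributions are compared across the four
outcome/electrode cells (seizure-free vs not × SOZ vs non-SOZ) with
Welch two-sample t-tests, Bonferroni-corrected for the family of 24
comparisons (6 bands × 4 pairs). Welch rather than pooled-variance was
chosen deliberately: with the group summaries this package works from,
the pooled test would understate the variance imbalance between outcome
groups (`welch_from_summary()` exists precisely to test published group
summaries). Degenerate cells (n < 2) are flagged in the output, never
silently dropped.

For outcome prediction, the electrode power distribution of each group
is reduced to deciles (10th…100th percentiles, linear interpolation —
`quantile type 7`; the convention is stated because decile values depend
on it). Within each band, group and window the ten decile values are
min–max mapped to [1, 10]; a degenerate all-equal profile maps to 1
everywhere so that the SOZ/non-SOZ ratio is 1 (uninformative) rather
than undefined. Ratios are therefore always in [0.1, 10].

## The stacked ensembles

Both classifiers share one architecture: six random forests of 100
trees, one per band, whose probability outputs are combined by a
penalized logistic GLM. Three choices deserve comment:

* **Stacking hygiene.** The meta-learner is trained on *out-of-fold*
  base probabilities from a 5-fold stratified internal CV inside each
  training set, never on in-sample fits — otherwise the meta-learner
  would reward the most overfit base model.
* **Forest growth.** Probability forests are grown to purity
  (`min.node.size = 1`, the classification-forest convention). The
  larger default terminal-node size of probability forests would leave
  small stacking folds unsplit and return the class prior.
* **Meta-penalty.** SRFE-electrode uses ridge (α = 0) with λ chosen by
  cross-validated deviance (stratified folds; if the minority class has
  fewer than 3 rows the search falls back to a fixed modest penalty).
  SRFE-outcome uses α = 0.5, λ = 0.1 fixed — its decile-ratio features
  are already normalized and a λ search on a handful of patients would
  be noise.

**Thresholding.** Electrode labelling maximizes true positives subject
to PPV ≥ 0.95, prioritizing specificity because a false-positive SOZ
label risks resecting healthy tissue. Candidate thresholds are the
sorted unique predicted probabilities (plus a sentinel above the
maximum, i.e. "label nothing"), which makes the tuning an exact finite
search verifiable against brute force; ties break toward the lower
threshold for determinism. If no candidate meets the constraint, nothing
is labelled positive and the result carries a flag. Outcome prediction
maximizes accuracy with the same grid; a PPV-constrained mode is
available for it behind `threshold_mode = "ppv"` since both criteria are
defensible for that model.

**Evaluation.** Leave-one-patient-out CV: the held-out patient's rows —
all seizures, all electrodes — are absent from base training,
meta-training *and* threshold tuning of that fold; the fold audit
(train/test patient-id intersection empty) is asserted programmatically
and retained in the result object. Per-seizure binary calls are
aggregated per patient (electrode) by majority voting with the ≥ 50%
rule: an exact tie is called positive. Baselines: a single forest on all
6 × 36 features ("simple RF") and the unweighted mean of the six
per-band probabilities ("averaged RF"), tuned identically.

Electrode features are raw ictal band power — no baseline normalization
and no log transform, matching the μV²/Hz export convention; rows are
electrode × seizure instances pooled across seizures for training.

## The synthetic cohort generator

The generator exists so that every stage — including the full LOPO
ensemble — can be exercised against known ground truth. It emulates:

* **Background**: independent per-channel Gaussian noise with a 1/f^β
  amplitude spectrum (β default 1, flat below 0.5 Hz), scaled exactly to
  a target RMS (default 50 μV), plus a mains line component (60 Hz
  default, configurable to 50 Hz). Sampling ≥ 500 Hz so the 150 Hz band
  edge is well below Nyquist. Records default to 60 s pre-onset + 30 s
  post-onset so both analysis epochs always fit.
* **Onset morphologies**: the eight canonical seizure-onset classes
  (A–H: low-voltage fast activity, preictal spiking + LVFA, polyspike
  bursts + LVFA, slow wave + LVFA, rhythmic slow spikes, theta/alpha and
  beta sharp activity, delta-brush) as additive deterministic
  sinusoid/burst templates with amplitude envelopes, scaled by a gain ×
  channel-RMS factor. The published taxonomy is qualitative; template
  parameters (chirp range 30–150 Hz, spike widths, carrier frequencies)
  are this module's defaults chosen so each class concentrates power in
  its declared carrier bands, which the test suite verifies spectrally
  (ictal/baseline ratio > 2 in a carrier band at gain 3, < 1.5 on
  untouched channels). They are emulations of the spectral signature
  only, not biophysical simulations — sufficient because every
  downstream stage consumes band power.
* **Cohort structure**: per-patient constant true-SOZ sets; clinician
  labels derived by dropping a `label_noise` fraction of true-SOZ
  channels; outcome = seizure-free iff the labels cover the true SOZ
  (resecting what the labels say then removes the onset zone).
  `label_noise` accepts a per-patient vector so one cohort can contain
  both outcome classes — needed for any outcome-model exercise, since a
  scalar noise level forces a single outcome for everyone.

It does **not** emulate volume conduction, electrode geometry, seizure
propagation across channels, non-stationary artifacts, or
patient-to-patient spectral variability. Passing tests on these cohorts
therefore demonstrate correctness of the pipeline's computations and
sound cross-validation, not clinical-grade performance: the synthetic
SOZ signature is far cleaner than real ictal iEEG, which is why the
synthetic ensemble reaches ROC AUC ≈ 1 while sensitivity on real
cohorts is known to be much lower at high-PPV operating points.

## Numerical conventions and edge cases

* Determinism: generators, forests (fixed seeds, single-threaded) and
  fold assignments are pure functions of the supplied seeds.
* Confusion metrics with zero denominators (e.g. PPV with no positive
  calls) are `NA` plus an `undefined` flag — never silently 0.
  Percentages print at one decimal, rounding half away from zero.
* ROC AUC uses midranks, so ties contribute one half; it equals the
  all-pairs count exactly.
* Variable importance is the forests' impurity decrease, normalized to
  sum 1 within each band; an all-zero band maps to the uniform profile.
  Permutation importance was considered and rejected as the default for
  cost; the normalization (per-band sum-to-one) is this package's
  convention.
* A single-class training fold in LOPO (possible in tiny or heavily
  imbalanced cohorts) predicts the constant class and is recorded in
  `flagged_folds` rather than aborting the whole CV.

## Problem sizes

The shipped tests run the full pipeline on cohorts of 8 patients × 40
channels (4 true SOZ) × 2 seizures at 500 Hz over 5 seeds — large enough
that each LOPO fold trains on ~560 electrode × seizure rows while the
whole suite stays comfortable on a laptop. The same configuration backs
`scripts/acceptance.R`, which reruns one seed end to end.

## Known limitations

* The plain-matrix text dialect (+ JSON sidecar and BIDS-style
  events/channels/patients TSVs) is the only on-disk recording format;
  BrainVision triplets are not written.
* Baseline-normalized or log-power features are not the default path
  (log10 is a documented possibility for heavy-tailed power
  distributions but the shipped models consume raw power).
* No hierarchical modelling of patient clustering in the group
  statistics; patient effects are handled only by the per-seizure AUC
  unit of analysis and by patient-level cross-validation in the models.
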