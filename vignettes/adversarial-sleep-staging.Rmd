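---
title: "Adversarial domain-generalized sleep staging: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial domain-generalized sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automatic sleep staging assigns one of the five AASM stages — Wake (W), N1,
N2, N3 and REM — to every 30-second epoch of an overnight polysomnography
(PSG) recording. Models trained on a fixed set of subjects often degrade
sharply on a *new* subject: EEG is non-stationary and amplitude, spectral
peaks and noise levels differ substantially between people. `adgsleep`
implements a domain-generalization answer to this problem: treat every
training subject as a *source domain* and train the feature extractor so that
its features are informative about sleep stage but uninformative about which
subject they came from. An unseen subject (the *target domain*) then receives
features that transfer.

## The model

Each 30-s epoch is represented as a 10-channel time-frequency image
$X^{TF} \in \mathbb{R}^{128 \times 128 \times 10}$ (6 EEG, 2 EOG, 1 EMG,
1 ECG). Three players share a feature extractor $G_f$:

* **Feature extractor** (`feature_extract()`): a U-shaped residual
  channel-attention network. The encoder stacks four stages of residual
  channel-attention blocks (Res-CAB); each block computes a 3×3 convolution
  $o_c = v_c * X$, recalibrates it with a squeeze-and-excitation (SE) module
  — squeeze $z_c = \frac{1}{HW}\sum_{i,j} o_c(i,j)$, excitation
  $s = \sigma(W_2\,\delta(W_1 z))$, scale $\tilde o_c = s_c o_c$ — and adds a
  shortcut before a ReLU: $y = \delta(\tilde o_c + x)$ (identity shortcut) or
  $y = \delta(\tilde o_c + f(x, W))$ (1×1 projection shortcut on strided /
  width-changing stages). The encoder maps (128, 128, 10) → (8, 8, 256). The
  decoder upsamples twice with skip concatenation from the equal-resolution
  encoder stages and 1×1 fusion convolutions, collapses the height axis by a
  mean, and feeds the resulting 32-step, 256-feature sequence to a
  bidirectional GRU (hidden 128 per direction), producing the feature
  sequence $\mathcal{F} \in \mathbb{R}^{32 \times 256}$.
* **Stage classifier** (`label_predict()`): three fully connected layers on
  the flattened sequence ending in a 5-way softmax, trained with
  cross-entropy $\mathcal{L}_{cla}$.
* **Domain discriminator** (`domain_predict()`): the same three-layer shape
  ending in an $n$-way softmax over the training subjects (9 for a
  10-subject cohort), trained with cross-entropy $\mathcal{L}_d$.

A **gradient reversal layer** (GRL, `grl_forward()` / `grl_backward()`) sits
between extractor and discriminator: identity in the forward pass, gradient
multiplied by $-\lambda$ in the backward pass. The discriminator therefore
descends $\mathcal{L}_d$ on its own weights while the extractor *ascends* it,
optimizing the overall objective

$$\mathcal{L}_{all} = \mathcal{L}_{cla} - \lambda\, \mathcal{L}_d.$$

All forward *and* backward passes are written in base R linear algebra
(im2col convolutions, BPTT through the GRU); there is no autodiff framework
underneath. The backward implementation is validated against central finite
differences at relative tolerance 2e-4 in the test suite, which we consider
the load-bearing correctness evidence for the whole training stack.

## Preprocessing

Recordings are resampled to 128 Hz (anti-aliased polyphase resampling;
upsampling is refused), split into contiguous, non-overlapping 30-s epochs
(trailing remainder dropped), and each channel is transformed with an STFT
using a 128-sample Hamming window, hop 64, no boundary padding, one-sided
magnitude: exactly 65 frequency bins × 59 frames. Choices the source protocol
leaves open, pinned here:

* **65 × 59 → 128 × 128** by separable bilinear interpolation with aligned
  endpoints (crop/pad alternatives discard frames or inject zeros).
* **Frame count**: no boundary padding, so the shape is independent of
  library padding dialects.
* **log(1 + x)** compression of the magnitude, since spectrogram dynamic
  range spans orders of magnitude.
* **Per-channel z-scoring with training-fold statistics only** — the held-out
  subject never contributes to normalization (leakage-free under LOSO).
* Stage label encoding W=0, N1=1, N2=2, N3=3, REM=4 everywhere.

## The synthetic cohort generator

No external PSG is required anywhere in the package: `generate_cohort()`
synthesizes multi-subject pseudo-PSG whose five stage signatures mirror
textbook physiology — W: 8–12 Hz alpha with high muscle tone; N1:
low-amplitude theta; N2: theta plus ~2 spindle bursts (13 Hz, 1 s) per epoch
and slow K-complex-like transients; N3: high-amplitude 0.5–2 Hz delta; REM:
theta with near-atonic EMG and large slow EOG deflections. Channels are a
fixed 6 EEG + 2 EOG + 1 EMG + 1 ECG montage. Hypnogram labels are i.i.d.
draws from a configurable stage distribution (default approximates overnight
proportions: 12/8/40/20/20%); the classifier treats one epoch as one sample,
so no stage-transition structure is modeled.

Per-subject **domain shift** has three components, all scaled by a single
`shift_magnitude`: log-normal per-channel gains (sd 0.75 at magnitude 1), a
global oscillation-frequency offset (sd 1.5 Hz), and a log-normal noise-floor
scale (sd 0.9). These scales were calibrated against the generator's own
contract: at the default magnitude a classifier trained on the other subjects
must measurably degrade on the held-out subject (we observe training accuracy
near 1.0 against held-out accuracy around 0.75 at desk scale), while a
learning-free bandpower nearest-centroid rule still classifies stages within
one subject at > 0.6 accuracy — the staging problem stays solvable, the
transfer problem stays non-trivial.

What the generator does **not** emulate: real inter-subject anatomy,
arousals, apnea events, stage-transition dynamics, artifacts, electrode
drift. Passing tests on synthetic cohorts therefore demonstrate that the
pipeline, optimization and adversarial mechanics work as specified — not that
the published accuracies on real PSG are reproduced.

## Training protocol

Full-scale defaults follow the published protocol: Adam (β₁ = 0.9,
β₂ = 0.999), learning rate 2e-5, batch size 16, 150 epochs, leave-one-
subject-out (LOSO) cross-validation with one fold per subject and fold
metrics averaged for the headline result. Choices the protocol leaves open:

* **λ = 1.0, constant** by default; an optional DANN-style ramp
  λ(p) = 2/(1 + e^{−10p}) − 1 over training progress is available
  (`lambda_schedule = "dann_ramp"`). λ = 0 detaches the adversarial signal.
* **Batch composition**: the pooled multi-source set is reshuffled each
  epoch; no per-domain balancing, no class weighting, no early stopping, no
  LR schedule.
* **Desk-scale profile** (`model_config_desk()`): 32 × 32 average-pooled
  input, stage widths 8/16/16/16, GRU hidden 16, heads 32/16, Adam at 1e-3
  (the conventional Adam scale for small networks — at 2e-5 a reduced model
  barely moves within a desk-scale epoch budget). Same architecture, same
  contracts, minutes instead of days on one CPU.
* **Fine-tuning** (`fine_tune()`): encoder and decoder convolutions (with
  their SE modules) are frozen bit-exactly by default; the Bi-GRU and heads
  retrain, and the domain head is rebuilt when the new cohort's training-
  subject count differs.
* The domain cross-entropy sums over the *domain classes* (the analogous
  stage-loss form reuses its symbols loosely in the source description; we
  read both sums as running over the respective class sets).

## Numerical choices and degenerate inputs

* Cross-entropy clamps probabilities at 1e-12 (warning logged) so a zero
  probability on a true class is a large finite loss, not `Inf`.
* Zero-denominator precision/recall/F1 return 0 with a `degenerate` flag so
  an absent class cannot poison the macro-F1 with NaN.
* Normalization floors channel standard deviations at 1e-8; a constant
  channel maps to exactly zero.
* Glorot-uniform initialization from the run seed; every random stream
  (cohort, hypnogram, epoch noise, shuffling, bootstrap) derives from one
  master seed through a multiplicative-congruential seed chain, so full runs
  are bit-reproducible.
* κ returns 1 in the degenerate p_e = p_o = 1 case; the bootstrap is the
  percentile method over epoch-level prediction pairs, B = 1000 at full
  scale (unit, B and method pinned here because the source protocol states
  only "bootstrap, 95%").

## Evaluation

Per fold: 5 × 5 confusion matrix (rows = truth), per-class
precision/recall/F1, accuracy, macro-F1 (unweighted mean of the five class
F1s), Cohen's κ = (p_o − p_e)/(1 − p_e), and a percentile-bootstrap CI for
accuracy. Across folds: unweighted means (the headline), the per-fold
accuracy vector, and a pooled confusion matrix reported alongside for
transparency.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run entirely on synthetic cohorts
at desk scale: 3-subject × 10–16-epoch cohorts for pipeline and
orchestration checks, and the adversarial-vs-plain comparison on 6 subjects
× 20 epochs with the reduced model, 30 training epochs and 5 seeded
replicates. At these sizes the directional benefit of the adversarial branch
is visible but noisy: medians across 5 seeds can tie, and individual seeds
can go either way (held-out sets are 20 epochs, so one epoch is 5 accuracy
points). The full-scale preset (`inst/configs/paper.yaml`) keeps the
published protocol and is the configuration one would run on a GPU-class
budget with real recordings.

## Known limitations

* The published architecture is specified only by its end shapes and
  parameter counts; the block counts and widths here are the minimal
  structure satisfying the documented shape chain, and the total parameter
  count intentionally does not match the published 15.12 M.
* Which 10 of the 12 montage channels the reference study used is unstated;
  the synthetic montage fixes 6 EEG + 2 EOG + 1 EMG + 1 ECG.
* Training is single-threaded R; the full-scale profile is provided for
  completeness, not speed.
* No EDF reader is bundled (no reader among the package's dependencies);
  cohort I/O is CSV signal + CSV hypnogram + JSON domain sidecar.
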