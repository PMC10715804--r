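---
title: "Contrastive world-representation learning for multichannel physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive world-representation learning for multichannel physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sleep staging assigns each 30-second window ("epoch") of a multichannel
EEG recording to one of five stages (W, N1, N2, N3, R).  Deep classifiers
do this well when large labeled corpora exist, but most recordings are
unlabeled: expert annotation is the bottleneck.  Self-supervised
contrastive learning sidesteps labels by training an encoder so that two
randomly perturbed *views* of the same epoch map to nearby points in a
representation space.  The catch is the negative side of the objective:
conventional methods push apart views of *different* epochs, but without
labels those "negatives" are random draws that frequently belong to the
same latent stage, which actively degrades the representation — the
more so the noisier the data.

`contrawr` implements an alternative: instead of many random negatives,
each anchor is contrasted against a single **world representation**, the
average projection of the current batch.  The average is a stable,
label-free summary of "everything", so pushing away from it cannot
single out a same-class sample for repulsion.

## The objective

Every epoch `x` (a C×N matrix) is augmented into two views, encoded by
`f(·)` to a d-dimensional representation `h`, projected by `g(·)` to an
m-dimensional vector, and L2-normalized onto the unit hypersphere.  The
anchor `z'` comes from the *online* network, the positive `z''` from a
*target* network.  Similarity on (the closed ball spanned by) the sphere
is a Gaussian kernel

    sim(a, b) = exp(-||a - b||^2 / (2 sigma^2)),

a strictly increasing function of cosine similarity on unit vectors — it
preserves cosine ordering at any width and flattens toward it as `sigma`
grows.  With the batch-mean world representation `zw`, each anchor
contributes a hinge ("triplet") term

    L = max(0, sim(z', zw) + delta - sim(z', z'')),

zero exactly when the positive similarity beats the world similarity by
the margin `delta`.  The online parameters descend this loss; the target
parameters follow by exponential moving average,
`phi <- lambda * phi + (1 - lambda) * theta`, and neither `z''` nor `zw`
receives gradients.  The slow target branch is what keeps the objective
from collapsing to a constant representation.

The **instance-aware** variant (`mode = "contrawr_plus"`) replaces the
uniform batch average by a per-anchor softmax-weighted average with
weights proportional to `exp(<z_k, z'> / T)`.  Samples near the anchor
dominate, making the negative reference "harder".  Two limits anchor the
implementation and its tests: `T -> Inf` recovers the uniform mean, and
`T -> 0+` collapses onto the anchor's nearest batch member.  A third
mode, `avg_knn_topx`, averages the anchor's top-X nearest batch members;
at `X = M` it coincides (bitwise, in this implementation) with the
uniform mode, so the three modes form a family ordered by negative
hardness.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 2 | Gaussian kernel width |
| `delta` | 0.2 | hinge margin |
| `temperature` | 2 | softmax temperature of the instance-aware weights |
| `ema_lambda` | 0.99 | target-network decay |
| `lr` | 2e-4 (reference) / 1e-3 (desk) | online learning rate |
| `weight_decay` | 1e-4 | L2 penalty folded into the gradient |
| `batch_size` | 256 (reference) / 32 (desk) | M |

Because two similarities sharing an anchor can differ by at most
`1 - exp(-2^2 / (2 sigma^2))` — about **0.3935** at `sigma = 2` (the
maximal unit-sphere distance is 2) — margins below about 0.1 leave the
hinge almost no room; `contrastive_config()` warns (but does not error)
for `delta < 0.1` at `sigma = 2`.  The kernel exponent uses the
`2 sigma^2` convention throughout; that convention is the one consistent
with this bound.

## Architecture

The encoder is a spectrogram CNN: an STFT magnitude spectrogram per
channel (Hann window, `log(1+·)` compression, per-epoch
standardization), one 3×3 convolution, then three blocks of
(3×3 convolution → ELU → 2×2 max-pool), then a global average pool, so
`d` equals the final width.  The projector is a 2-layer ELU perceptron
onto m dimensions followed by L2 normalization.  The supervised
reference model replaces the projector with a 2-layer softmax head and
trains end to end on labels only.

The forward and backward passes are implemented in the package itself
(the convolutional core in C++ via RcppArmadillo, the rest in R, with an
Adam optimizer), and the backward pass is verified against central
finite differences in the test suite.  One deliberate asymmetry: in the
instance-aware mode the softmax weights depend on the anchor, but the
world representation is treated as a constant under differentiation
(stop-gradient), exactly as the positives are — the target side of the
pipeline never propagates gradients.

Two size profiles are bundled.  The `"paper"` profile is the reference
configuration (widths 8-16-32-64, d = 64, 2-second STFT window,
batch 256, 100 passes, lr 2e-4).  The `"desk"` profile is the package's
own scaled evaluation condition, chosen once for interactive use: widths
4-8-16-32 (d = 32), a 1-second window with 2-second hop (51×15
spectrogram), batch 32, 30 passes, lr 1e-3 (the shorter schedule and
smaller net converge faster at a higher rate).  All results quoted in
this vignette and in the test suite use the desk profile.

## Augmentations

Four label-preserving perturbations, composed per view by drawing a
uniformly random non-empty subset of the enabled operations:

* **bandpass** (default 0.5–30 Hz): an order-1 Butterworth bandpass
  applied zero-phase, implemented in the frequency domain as the squared
  Butterworth magnitude response, circularly — so it introduces no time
  shift, no edge transients, and commutes exactly with the circular
  shift below.
* **noising** (default SNR drawn from 5–20 dB per view): Gaussian noise
  confined to a low (0–2 Hz) or high (fs/4–fs/2) band — the band choice
  is part of the seeded draw — scaled per channel to the target
  signal-to-noise power ratio.
* **flipping**: swapping symmetric (left/right) channel pairs.  A flip
  alone produces a view that is statistically indistinguishable from a
  real epoch of the same class, so the policy never applies flipping as
  the sole operation; under the uniform-subset rule with all four
  operations enabled, flipping occurs with probability exactly 1/2 per
  view.
* **shifting** (default up to fs/2 samples): a circular time shift,
  which preserves per-channel energy and spectrum exactly.

Whether the original experiments composed augmentations per view or
applied one at a time is not fixed by their description; the uniform
random-subset policy is this package's choice, made for symmetry and
because compositions were reported beneficial.  Exact per-dataset
augmentation settings were likewise not available, so the defaults above
are standard sleep-EEG choices and everything is configurable through
`augmentation_policy()`.

## Evaluation protocol

`pretrain()` never reads labels (they are stripped on entry).
Evaluation follows the standard frozen-encoder protocol:
`linear_probe()` encodes the labeled training epochs with the frozen
encoder, fits a ridge-penalized multinomial logistic regression
(`glmnet`, penalty chosen by accuracy on a stratified fifth of the
training rows — "a good logistic classifier" is read as light,
deterministic tuning), and reports overall accuracy plus a confusion
matrix on the held-out test epochs.  The control is
`untrained_baseline()`: the identical architecture, randomly
initialized, probed the same way.  Splits are always at the subject
level (`split_subjects()`), because epochs of one subject are strongly
correlated; the desk evaluation uses 50 % pretrain / 25 % train / 25 %
test, which at 40 subjects leaves 10 subjects in each labeled split.

`label_fraction_sweep()` repeats pretrain + probe and the supervised
reference while the labeled fraction varies and the test subjects stay
fixed, the protocol behind the observation that self-supervision wins
when labels are scarce.

## The synthetic generator

`generate_dataset()` draws K = 5 classes of multichannel epochs whose
classes differ by spectral content, echoing canonical stage signatures:
alpha (10 Hz) for W, low-amplitude theta (6 Hz) for N1, sigma (13 Hz)
for N2, high-amplitude delta (1.5 Hz) for N3, and a 5 + 20 Hz mixture
for R.  Each epoch is band-limited Gaussian noise at the class bands
(RMS-calibrated), shared within mirror channel pairs so channel flipping
is label-preserving, plus independent white noise per channel
(`noise_sd = 1.5`, chosen once so the task is noisy but solvable — a
bandpower + logistic baseline reaches ≥ 0.9), a per-subject log-normal
gain (`subject_effect_sd = 0.2`) and a per-subject spectral shift
(`subject_freq_jitter = 0.25` Hz) that give subjects a shared
fingerprint and make subject-level splitting consequential.  Defaults:
40 subjects × 50 epochs of 4 channels × 3000 samples at 100 Hz, labels
cycling through the classes.

What the generator does **not** emulate: sleep-architecture dynamics
(stage transitions and durations), artifacts (EMG/EOG contamination,
electrode pops), 1/f background spectra, and montage-specific channel
geometry.  Passing tests on this generator therefore demonstrate that
the optimization and protocol behave as designed on spectrally
separable, subject-structured data — not that any particular accuracy
carries over to recorded polysomnograms.

## Numerical choices and degenerate inputs

* Frame count of the STFT is `floor((N - window)/hop) + 1`; trailing
  partial frames are dropped.  Spectrogram standardization guards
  against zero variance (constant epochs) by leaving such spectrograms
  at zero.
* `project()` refuses a (near-)zero pre-normalization vector rather than
  normalizing it; the softmax in the instance-aware weights is
  max-stabilized, so extreme temperatures are safe.
* Ties in the top-X neighbour selection break by ascending batch index,
  and the selected members are summed in index order — which is what
  makes `X = M` bitwise equal to the uniform mean.
* Whether each anchor's own positive belongs in the world average is not
  settled by the method's description; the batch mean includes it by
  default (the unbiased estimate of the batch distribution) and
  `exclude_self = TRUE` switches it off.
* Mini-batches are sampled without replacement each pass and a trailing
  partial batch is dropped, so every gradient step sees exactly M
  samples.
* All randomness (initialization, batch order, augmentation draws,
  probe carve-outs, the generator) flows from explicit seeds; two runs
  with equal seeds produce bitwise-identical loss histories.

## What the desk-scale experiments show

On the default synthetic dataset, desk profile, 30 passes: the
contrastive loss descends after a brief warm-up (the target network
needs some steps before positives become informative), and the frozen
pretrained encoder's probe accuracy exceeds the untrained encoder's in
paired seeds by a wide margin (≈ 0.98 vs ≈ 0.48 in the worked example of
the README).  The label-fraction sweep (80 subjects × 10 epochs, 8
passes, 3 seeds — sized so even the 1 % training split has at least two
epochs of every class, the minimum the probe's ridge regression
accepts) shows probe accuracy non-decreasing in the labeled fraction
while the from-scratch supervised reference, with so few labels and
passes, stays near chance.  These are exactly the properties the test
suite asserts; no number in this vignette comes from anywhere else.

## Limitations

* The convolutional core is plain single-threaded CPU code; the
  reference profile (batch 256, 100 passes) on millions of epochs is out
  of desk reach, which is why the desk profile exists.
* Only the world-representation family of objectives is implemented;
  queue/memory-bank and predictor-head methods are other families, kept
  out of scope.
* The EDF reader covers the plain EDF core (one sampling rate per
  selected channel set, 16-bit records); EDF+ annotations are ignored.
* The probe's penalty grid is small and fixed; it is meant to be a fair,
  deterministic read-out, not a squeezed-out classifier.
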