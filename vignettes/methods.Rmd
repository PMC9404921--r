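---
title: "Contrastive self-supervised learning for ECG stress detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive self-supervised learning for ECG stress detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Stress and affect leave a strong autonomic signature in the electrocardiogram:
sympathetic activation raises heart rate and suppresses beat-to-beat
variability. Supervised stress classifiers need labeled ECG, and labels are
the expensive part — experimental protocols with controlled stressors yield
small cohorts. `ecgclr` implements a SimCLR-style contrastive self-supervised
pipeline that first learns an ECG representation from *unlabeled* windows and
then fine-tunes a classifier on whatever labels exist.

The pipeline has two stages:

* **Upstream (pretext) task.** Each fixed-length segment $x$ is paired with
  an altered view $x'$ produced by stochastic, label-free augmentations. A
  siamese pair of networks — a shared 1-D CNN encoder $f(\cdot)$ producing
  representation $h$, followed by a projection head $g(\cdot)$ producing a
  contrast vector $z$ — is trained so that $z_x$ and $z_{x'}$ agree while
  differing from every other segment in the minibatch. Agreement is cosine
  similarity $\mathrm{sim}(z_1, z_2) = z_1^\top z_2 / (\lVert z_1\rVert\,
  \lVert z_2\rVert)$, and the objective is the normalized temperature-scaled
  cross-entropy (NT-Xent): with $N$ segments per batch and hence $2N$
  embeddings, the loss for anchor $x$ with positive $x'$ is

  $$\ell_{x} = -\log \frac{\exp(\mathrm{sim}(z_x, z_{x'})/\tau)}
  {\sum_{y \ne x}^{2N} \exp(\mathrm{sim}(z_x, z_y)/\tau)},$$

  averaged over all $2N$ anchors; each anchor sees one positive and $2(N-1)$
  negatives. No ground-truth labels enter this stage (the test suite checks
  that shuffling labels leaves the loss history bit-identical).

* **Downstream task.** A classifier with an architecturally identical
  encoder, initialized from the pretrained $f(\cdot)$ weights (the projection
  head is discarded), plus a softmax head with one unit per class, is
  fine-tuned end-to-end with cross-entropy. The comparison arms are the same
  CNN from random initialization (fully supervised) and an RBF-SVM on nine
  classical HRV features.

## Architecture

The encoder has three convolutional blocks — one convolution per block with
ReLU, filter counts 32/64/128 and kernel widths 32/16/8, each followed by
max-pooling and dropout — then a per-time-position dense layer of 80 units
with an L2 weight penalty, and a flatten. The projection head is a single
256-unit layer with softmax activation.

Two points in this architecture are stated ambiguously in its source
tradition and were resolved as follows:

* *"L2 regularization of size 3"* is interpreted as an L2 weight-penalty
  coefficient of 3.0 on the 80-unit dense layer (configurable via
  `encoder_config(l2_coeff = )`). Under Adam the penalty's practical effect
  is modest because updates are magnitude-normalized.
* The *softmax projection head* constrains $z$ to the probability simplex, so
  cosine similarities between embeddings live in $(0, 1]$ rather than
  $[-1, 1]$. We honor the stated design; a linear head is available behind
  `projection_config(activation = "linear")` for ablation.
* The dense-then-flatten order is honored by applying the 80-unit layer per
  time position (a width-1 convolution) before flattening. The dense layer
  uses ReLU activation, the convention of the architecture family it
  belongs to.

No deep-learning framework is involved: forward and backward passes (im2col
convolutions lowered to BLAS matrix products, with compiled gather/scatter
kernels), the NT-Xent gradient, and the Adam optimizer are implemented in the
package and verified against finite differences and a brute-force loss oracle
in the test suite.

## Preprocessing chain

The order is fixed: resample → high-pass → per-subject z-score → saturation
clip → window → (optional) SMOTE.

* **Resampling** to 256 Hz uses polyphase rational resampling with an
  anti-aliasing FIR (e.g. 700 Hz sources use the exact ratio 64/175).
* **Baseline-wander removal**: order-4 Chebyshev type-II high-pass, 40 dB
  stop-band attenuation, stop-band edge at 0.8 Hz, applied forward-backward
  (zero phase) so R-peak timing is not shifted. The record mean is removed
  first, so DC rejection is exact; the 5 Hz pass-band gain deviates from
  unity by well under 5%.
* **Z-scoring** is strictly per subject; no statistics are pooled.
* **Saturation clipping** truncates at ±10 SD by default (configurable).
  The source protocols clip "where saturation was observed" without a rule;
  a fixed symmetric bound on the z-scored trace is the reproducible choice.
* **Windowing** cuts non-overlapping windows (10 s for long-record
  protocols, 5 s for short ones; stride configurable). Windows spanning a
  condition change are discarded — mixed-label supervision is ambiguous and
  the loss of a few boundary windows is immaterial.
* **SMOTE** balancing grows each minority class to the majority count with
  convex combinations $s_i + u\,(s_j - s_i)$, $u \sim U(0,1)$, of a minority
  segment and one of its 5 nearest minority neighbours. Original rows are
  preserved verbatim. With class counts 242/88/48 the balanced total is
  726 segments. The default applies SMOTE before splitting, reproducing the
  protocol it emulates; `smote_train_only` in the run configuration is the
  leakage-safe alternative.

## Augmentations

Six label-free operators create the altered view: amplitude scaling
($c \sim U(0.5, 2)$), negation, horizontal flip (time reversal), additive
Gaussian noise at a 15 dB target SNR, permutation of 20 contiguous chunks,
and smooth time warping (4 interior knots, knot speeds $\sim N(1, 0.2^2)$
clipped positive, spline-interpolated into a monotone time map). Magnitudes
are not prescribed by the protocol this follows; the defaults are the
conventions of the time-series SSL literature and all are configurable. One
branch of the siamese pair receives the unaltered segment, the other the
augmented view, and views are redrawn freshly every epoch so the pretext
task cannot memorize fixed pairs. The composition found most effective for
affect detection — time warping followed by scaling — is the default
pairing.

## Synthetic data generator

Real stress-ECG corpora are either large external downloads or private, so
the package carries a generator whose output exercises every pipeline stage:

* Beats are a five-Gaussian P-Q-R-S-T template placed at RR-interval onsets;
  widths and offsets scale with the instantaneous RR so fast beats stay
  morphologically plausible. A full dynamical ECG model would add realism the
  pipeline does not need — what matters is R-peak detectability and
  rate/variability structure.
* The RR series is $60/(\mathrm{HR}_0 + \Delta \mathrm{HR}(c))$ plus AR(1)
  jitter (coefficient 0.8, short-range correlation) with condition-dependent
  stationary SD. The defaults encode the canonical stress signature:
  conditions 0/1/2 shift heart rate by 0/+12/+25 beats/min while RR jitter
  falls 50/35/20 ms. Sub-0.5 Hz sinusoidal baseline wander, white sensor
  noise, and an optional hard saturation ceiling complete the record.
* Per-subject perturbation draws resting heart rate from U(62, 78) beats/min
  — wide enough that subject identity overlaps condition effects, as in real
  cohorts.
* When a target class-count histogram is requested, block durations are
  exact window multiples distributed across subjects, so windowing
  reproduces the histogram (emulating imbalanced cohorts such as 242:88:48).

What the generator does **not** emulate: real QRS morphology variation,
ectopy and arrhythmia, electrode artifacts, respiratory sinus arrhythmia
spectra. Passing tests on this data demonstrates that the pipeline's
machinery — preprocessing contracts, representation learning, weight
transfer, evaluation protocol — behaves correctly; it does not certify
field accuracy on clinical ECG.

## Evaluation protocol

Downstream experiments use 10 independent random shuffled splits at a stated
test:train ratio ("Monte-Carlo cross-validation"). A ratio of "70-30" holds
out 70% and trains on 30% — the regime where pretraining helps most. Note a
partition-based k-fold cannot sweep ratios, which is why repeated random
splitting is the right reading of "10 folds with random shuffling". Folds
whose training half misses a class are redrawn (at most 5 times, logged by
seed bookkeeping). Accuracy is aggregated as mean ± SD *over folds*;
confusion matrices are pooled counts. Splits are segment-level, which
matches the emulated protocol but lets segments of one subject appear on
both sides; `subject_wise = TRUE` provides the leakage-safe variant, and the
two can differ substantially.

The two ablation harnesses mirror the study designs they reproduce:
`ratio_ablation()` sweeps ratios 0.1–0.9 for each single augmentation plus a
no-augmentation control (definitionally equal to the supervised baseline),
and `augmentation_grid()` evaluates all ordered pairs of augmentations
(diagonal = single) at the 70-30 split.

## HRV baseline

R peaks are detected Pan-Tompkins style (zero-phase 5–15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds, 200 ms refractory period) and refined to the
band-passed apex. The nine features are HR, RMSSD, AVNN, SDNN, pNN50 from
the RR series, and VLF/LF/HF band powers (0.0033–0.04, 0.04–0.15,
0.15–0.4 Hz) plus their sum TP from a Welch PSD of the 4 Hz-interpolated,
linearly detrended RR series. Frequency features require a 30 s span and are
reported missing — never zero — on shorter windows, so 5 s segments fall
back to the five time-domain features. The SVM uses an RBF kernel with
C = 1, features standardized with training-fold statistics only.

## Numerical choices and degenerate inputs

* NT-Xent excludes the anchor's self-similarity from the denominator
  exactly; with $N = 1$ numerator and denominator coincide and the loss is
  exactly zero. Log-sum-exp is computed stably.
* Argmax ties in prediction break toward the lowest class index,
  deterministically.
* Weight initialization is Glorot-uniform with zero biases; all randomness
  (initialization, batch order, dropout, augmentation draws, splits) flows
  from explicit seeds, and every public entry point is bit-reproducible
  given its seed.
* Zero-variance records refuse to z-score; zero-power segments refuse SNR
  noise; records shorter than one window yield an empty segment set with a
  warning; single-member minority classes refuse SMOTE.

## Scaled-down study sizes

The test suite and the acceptance script exercise the full pipeline on
generator output sized to the package's own validation needs: 6 subjects at
256 Hz, 5 s windows (1280 samples), roughly 400 segments, three stress
levels. Upstream pretraining runs until the NT-Xent loss approaches its
plateau — 60 epochs at batch 32, learning rate 1e-4, temperature 0.1; the
softmax projection head scales gradients by roughly the inverse of its
width, so loss stabilization (the protocol's stopping criterion) arrives
later in epochs than it would with a linear head. Scaled-down fine-tuning
uses 30 epochs at batch 32 (learning rate 1e-3), enough for training-loss
convergence at ~120 labeled segments — at this scale a batch of 128 would
exceed the training set. The pretraining-benefit check compares fine-tuning
from pretrained versus random initialization on identical 70-30 splits over
five seeds and asks for a positive median difference, a deliberately
scaled-down stand-in for the large pretraining gains reported at that ratio
on real cohorts.

## Known limitations

* The hand-rolled CNN engine is CPU-only and single-threaded beyond BLAS;
  it is sized for method validation, not production training throughput.
* The softmax projection head compresses the contrast space; if
  representation quality on real data is the goal, the linear-head ablation
  is worth running.
* Segment-level splitting inflates accuracy relative to subject-wise
  evaluation whenever subject identity correlates with condition; both modes
  are provided.
* The generator's condition structure is rate/variability-based only;
  augmentation rankings measured on it need not transfer to real ECG.
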