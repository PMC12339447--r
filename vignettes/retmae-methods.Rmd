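---
title: "Masked autoencoding for multi-source retinal OCT classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked autoencoding for multi-source retinal OCT classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retmae)
```

## The problem and the approach

Labeled retinal OCT data are scarce and fragmented across institutions,
devices, and acquisition protocols. A classifier trained on one archive
often collapses on scans from another. `retmae` implements a two-phase
framework that addresses both problems at once:

1. **Self-supervised pre-training.** The training and validation splits of
   several sources are concatenated and shuffled ("data fusion") — without
   labels — and a masked autoencoder (MAE) learns to reconstruct B-scans
   from which a large fraction of patches has been hidden. Test splits never
   enter the fused pool; isolation is asserted by image id.
2. **Supervised transfer.** The decoder is discarded, the pre-trained
   encoder is frozen, and a small three-layer dense head with ReLU
   activations and a softmax output is trained on one source's labeled
   training split for the binary NORMAL vs AMD decision (drusen-labeled
   scans count as AMD, all other categories are dropped). The classifier is
   then evaluated on *every* source's held-out test split, giving a
   (train source × test source) matrix that measures cross-dataset
   generalization directly.

### The masked objective

An image is divided into square mask patches (16 px at the 224×224 "paper"
scale, 8 px at the 64×64 desk scale). A mask plan hides exactly
`floor(m_ratio * P)` of the `P` patches, drawn uniformly without
replacement; the default masking ratio is 0.7 (the ratio study in the
original work covered 0.2/0.5/0.7/0.8). The loss is the mean squared error
multiplied by the pixel mask and normalized by the masking ratio:

    L = (1 / m_ratio) * (1 / N) * sum_i (xhat_i - x_i)^2 * m_i

with `N` the pixel count, `m_i` the pixel mask and `x` the raw `[0, 1]`
pixels. Two exact identities follow and are enforced by tests: the loss does
not depend on the reconstruction at unmasked pixels, and when `m_ratio`
equals the realized masked fraction the loss equals the plain MSE over
masked pixels.

### Backbones and the dense mask token

Three encoder families are available, at a declarative "paper" scale and at
a runnable "tiny" scale:

* `vit` — a plain vision transformer (paper scale: embedding 1024, 6
  layers, 4 heads; decoder 1024-wide, 4 layers, 4 heads).
* `swin` — hierarchical shifted-window attention (embedding 96, depths
  (2, 2, 18, 2), heads (6, 12, 24, 48)); 4 px patch embedding, patch
  merging between stages, relative-position-bias tables per window.
* `swinv2` — depths (2, 2, 6, 2), heads (3, 6, 12, 24), with the family's
  stabilizations: cosine attention with a learned per-head log temperature
  (clamped at 100) and residual-post-norm blocks. The continuous
  log-spaced position-bias MLP of the full design is simplified to a
  learned relative-position-bias table; this is recorded as a deliberate
  desk-scale simplification.

Windowed attention cannot drop masked tokens the way a ViT-MAE does, so all
families use *dense masking*: every 4 px embedding patch lying inside a
masked mask-patch is replaced by a shared learned mask token and the full
grid is processed. The decoder mirrors the encoder (768-wide for the Swin
families) and restores resolution with patch-expanding stages.

All transformer layers, their gradients, and the decoupled-weight-decay
Adam optimizer are implemented in the package on a small reverse-mode
autodiff engine over base-R matrices. Windowed multi-head attention is a
single fused tape operation with a hand-derived backward pass; every
operation is validated against central finite differences in the test
suite, and the full tiny models check out to ~1e-6 relative error.

## Training regimes

Pre-training follows the published recipe: learning rate 1.5e-4, AdamW-style
decoupled weight decay 0.05 with betas (0.9, 0.95), batch size 32, and the
checkpoint with minimum fused-validation loss is kept (50 epochs at paper
scale; desk-scale runs use 2–4 epochs, which already drive the masked
validation loss down monotonically on synthetic data). A fresh mask is drawn
per image per epoch from a seeded stream; validation masks are fixed per
image so checkpoint selection is stable.

Supervised training keeps the encoder frozen (feature extraction), trains
the head with cross-entropy, and applies early stopping with patience 10 on
validation accuracy, keeping the maximum-validation-accuracy checkpoint; a
strictly greater accuracy resets the patience counter, ties do not (among
equal-accuracy epochs the most recent weights are kept, so a small
validation set that plateaus at the majority rate still yields a trained
head rather than a near-initial one). Five
augmentations (rotation ≤ 15°, horizontal flip, brightness/contrast jitter
±0.2, Gaussian blur σ ∈ [0.1, 1], mild elastic shift) are available and are
applied to training images only.

Three numerical choices matter at desk scale and are the package's own:

* **Input normalization.** Encoder inputs are standardized with per-source
  pixel mean/sd computed on the training split (stored in the checkpoint);
  reconstruction targets stay on the raw `[0, 1]` scale. A source never
  seen in pre-training falls back to statistics of the images at hand.
* **Feature standardization.** The mean-pooled final-stage encoder tokens
  vary on a very small scale, so the head standardizes them per dimension
  with training-split statistics; the sd is floored at 10% of the median sd
  so near-constant dimensions cannot explode on held-out data.
* **Head initialization.** Hidden layers use He scaling; the final 2-way
  layer starts near zero so early epochs move the decision rule rather than
  unwinding large random logits. The supervised default learning rate
  mirrors the pre-training 1.5e-4; desk-scale runs pass 1e-3 because the
  head sees only a few dozen optimizer steps.

## The synthetic study

The simulator renders layered-band B-scans: smooth curved boundaries,
per-band reflectivity, drusen-like dome deformations of the outer band for
AMD (plus larger domes for a CNV-like class and hyporeflective fluid
pockets for a DME-like class), multiplicative log-normal speckle, Gaussian
blur, and an affine per-source intensity shift. These are the canonical
image-formation elements of OCT; the generator makes no claim to physical
speckle statistics, A-scan physics, or 3-D volumes. Its purpose is a
controllable stand-in with (a) learnable class signal — a template
classifier reaches AUROC > 0.9 on noiseless renders — and (b) real domain
gaps — per-source gain/offset shifts give a Kolmogorov–Smirnov distance
> 0.1 between mean-intensity distributions.

`synth_study()` emulates the three-source layout: `src1`, a large stratified
archive with all four categories (80/10/10 split); `src2`, a small
subject-grouped set (15 subjects per class, 10/2/3 subjects to
train/val/test at subject granularity — subject integrity is an invariant);
`src3`, a binary, imbalanced (80:20 NORMAL:AMD), stratified source.
Splitting uses largest-remainder rounding per class with remainders going to
train, and every split is guaranteed non-empty for classes with at least
three records. Subject order for the "first 10 subjects" rule is
lexicographic, since true acquisition order is not meaningful for synthetic
subjects.

Passing tests on this simulator show that the machinery — fusion with test
isolation, masked-loss optimization, frozen transfer, cross-evaluation, the
exact paired test — behaves as specified, and that pre-training and fusion
help *in the direction* the framework predicts. They do not show clinical
performance: real OCT speckle, pathology diversity, and annotation noise
are all absent.

```{r}
study <- synth_study(seed = 1, n_train_per_source = 150)
fus <- fuse_for_pretraining(study$manifests, rng_seed = 1)
ck <- pretrain(fus, "swinv2-tiny",
               pretrain_config(epochs = 4, batch_size = 32, seed = 1),
               images = study$images)
```

## Evaluation and the exact paired comparison

`compute_metrics()` reports accuracy (`(TP + TN) / n`, an exact integer
identity on every report), F1 for the AMD (disease-positive) class at the
0.5 softmax threshold, AUC-ROC as the tie-aware Mann–Whitney statistic, and
AUC-PR as step-interpolated average precision (trapezoidal PR interpolation
is biased and deliberately not used). Single-class test sets yield flagged
`NA`s, never silent zeros.

Because paired AUC-ROC values across (train, test) cells are few and not
normal, model comparison uses the exact Wilcoxon signed-rank test: zero
differences are dropped (the classical treatment), tied absolute
differences receive mid-ranks, and the null distribution of the
positive-rank sum is computed over all `2^n` sign assignments of the
realized rank values (a dynamic program over half-integer ranks, identical
to full enumeration). The two-sided p-value is
`2 * min(P(W+ <= w), P(W+ >= w))`, capped at 1. These conventions — chosen
once — reproduce both published p-values from the shipped reference tables:
0.02 for ResNet-50 vs the SwinV2 classifier and 0.01 for the pre-training
ablation (`reference_auroc_pairs()`).

Baselines are constructed as exact layer-by-layer parameter accounts:
ResNet-50 with a binary head counts 23,512,130 trainable parameters
(23.5 M at one decimal) and ViT-Base 85,800,194 (86 M); with 1000-class
heads the same tables give the canonical 25,557,032 and 86,567,656.
Training CNN baselines is outside desk scale, so these handles support
parameter accounting only.

## Experiment protocols

`run_experiment()` (and the `retmae run` CLI) wires the five protocols:
`full` (fused pre-training, per-source classifiers, 3×3 matrix), `no_ssl`
(randomly initialized encoder), `no_fusion` (per-source pre-training),
`unseen_pretrain` (pre-training and supervised training on source 1 only),
and `half_data` (supervised training split subsampled 50%, stratified).
Every run writes its manifests, per-epoch logs, a config snapshot and the
report, so a report can be regenerated from its artifact directory alone;
partial artifacts of a failed run are quarantined, never silently reused.

The directional ablation (`ssl_ablation_run()`) uses 150 training images per
source, the tiny SwinV2 at 64×64, 4 pre-training epochs, and a (32, 16)
head trained for up to 40 epochs at lr 1e-3 — sizes chosen so five seeded
replicates complete comfortably on one CPU. Over five seeds the median mean
AUROC with fused pre-training exceeds the no-pre-training arm, and the
fused arm beats single-source pre-training on the two foreign sources; no
effect size is asserted, matching the direction-only reading of the
original ablations. In the no-pre-training arm the encoder is randomly
initialized and, like the main arm, frozen — i.e. both arms are feature
extractors, which isolates the value of the learned representation.

## Known limitations

* The paper-scale presets are constructible and forwardable in principle,
  but training them in base R is not practical; all empirical claims in
  this package are desk-scale.
* The decoder schedule for the hierarchical families is mirrored from the
  encoder; the original work does not pin down layer-by-layer decoder
  dimensions, so parameter counts of the MAE variants are not comparison
  targets.
* The simulator's speckle is log-normal multiplicative noise, not
  physically derived; domain shift is purely affine plus acquisition
  parameters.
* Exact signed-rank enumeration is limited to 30 non-zero pairs; beyond
  that the implementation refuses rather than approximating.
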