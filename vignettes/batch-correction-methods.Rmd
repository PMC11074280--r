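---
title: "Methods: adversarial autoencoders for batch-effect removal in LC-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial autoencoders for batch-effect removal in LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(batchae)
```

This vignette documents the modeling choices behind `batchae`: the
objective each model optimizes, what every tunable parameter means, the
numerical decisions that are invisible from the API, what the synthetic
generator does and does not emulate, and the limitations we know about.
It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and the model family

An LC-MS intensity matrix carries two overlaid structures: the biology of
interest (class labels) and the accident of acquisition (batches). We
want a per-sample embedding `z` in which a batch classifier is at chance
while a class classifier still works on *batches never seen in
training* — the only honest definition of "corrected" when downstream
models must be deployed on future batches.

All ten models share one architecture: a single-hidden-layer encoder
`x → ReLU(layer1) → z (layer2)`, a mirrored decoder, and a linear label
head on `z`. The single hidden layer is a deliberate capacity cap:
LC-MS cohorts are small (hundreds of injections), and deeper autoencoders
overfit batch idiosyncrasies faster than they learn biology. Variational
variants replace the bottleneck by parallel `μ` and `log σ²` heads with
`z = μ + σε`; the KL divergence to `N(0, I)` acts as a stochastic
regularizer and mild data augmentation. The full objective is

```
L_total = L_rec + ν·L_classif + β·KLD + γ·L_BE
```

with `L_BE` one of four batch-effect strategies (adversarial through a
gradient reversal layer; alternating min–max with a per-batch decoder
offset; inverse or reversed batch triplet loss).

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `layer1`, `layer2` | hidden and bottleneck width (units) | 64 / 16 | small relative to features; searched in practice |
| `ν` (`nu`) | weight of the label loss on the *encoder* | 1 | the head itself always minimizes plain CE; `ν` only scales the encoder-bound gradient, so `ν = 0` reproduces a frozen-representation protocol without silencing the head |
| `β` (`beta`) | KLD weight (variational only) | 1 | classic trade-off between reconstruction and posterior collapse |
| `γ` (`gamma`) | batch-loss weight; also the GRL scale | 1 | the GRL multiplies the encoder-bound batch gradient by `−γ`; the discriminator head trains on unweighted CE |
| `margin` (`α`) | triplet margin (distance units in `z`) | 1 | how far same-batch samples are pushed apart, preventing collapse to a point |
| `dropout` | rate on hidden layers *and on `z` for both heads* | 0.1 | head-input dropout keeps the batch discriminator imperfect, which keeps the adversarial gradient alive (see "Numerical choices") |
| `label_smoothing` | smoothed CE targets | 0 | regularizes the head on small cohorts |
| `warmup_epochs` | unsupervised epochs on the full dataset | 50 | transductive by design — no label is consumed |
| `learning_rate`, `weight_decay` | Adam with decoupled decay on weight matrices | 1e-3 / 1e-6 | Adam is the de-facto default for this family; the optimizer is not specified by the protocol itself |
| `normalization` | one of six variants: {minmax, standard, robust} × {global, per-batch} | standard | a *model hyperparameter*, not a fixed preprocessing step; the per-batch z-score variants are themselves location/scale batch-correction methods |
| training loop | minibatch 32, ≤ 1000 epochs, patience 100 on validation MCC | as stated | all overridable per call |

## Protocol

Warmup (step 1) trains every unsupervised component — autoencoder,
KL term, batch loss, discriminator — on *all* samples including
validation and test. This is transductive: embeddings may use the
held-out batches' unlabeled structure. We reproduce that protocol by
default because correcting a finished, fixed dataset is the dominant use
case; `normalize_omics(fit_on = ...)` and passing only training samples
to `warmup()` give a leakage-free variant for deployment studies.

Scenario 1 then freezes everything but the label head (tested as an
exact parameter-identity invariant). Scenario 2 alternates one
unsupervised epoch over everything with one supervised epoch over the
training batches whose gradients flow through the encoder; the
alternation granularity (per epoch) was an open choice — per-minibatch
alternation is a trivial variant but makes loss curves harder to read.
Early stopping requires *strict* improvement of validation MCC;
parameters of the best epoch are restored.

Splits are batch-disjoint by construction. Stratification assigns whole
batches by scoring random candidate assignments against the global class
proportions and keeping the best; with exactly three batches the repeats
rotate the batches through the three roles, which is the only
batch-disjoint design possible there.

## Numerical choices

- **Batch entropy**: Shannon entropy in nats with `0·log(1/0) := 0`. The
  normalization `(ln K − BE)/ln K` makes the value base-invariant. The
  dataset-level nBE is the *mean* of per-sample values (the aggregation
  is otherwise unspecified). KNN neighbourhoods include the query sample
  (matching a classifier fit and predicted on the same data);
  `include_self = FALSE` is available. KNN ties break by batch sort
  order, deterministically.
- **AMI normalizer**: arithmetic mean of the two partition entropies;
  `E[MI]` uses the exact hypergeometric expectation with `lgamma`.
- **Multiclass MCC**: generalized (Gorodkin) form; degenerate
  denominators return 0 with a message.
- **GRL as arithmetic, not autograd**: gradients are hand-derived, and
  the reversal is literally `grad ← −γ·grad` on the encoder-bound path of
  the batch CE; the discriminator's own parameters are never reversed.
  The suite verifies the analytic encoder gradient against central finite
  differences at 1e-6.
- **Heads train on unweighted CE**: `ν` and `γ` scale only encoder-bound
  gradients. Weighting a head's own gradient by its loss weight would
  merely rescale its effective learning rate and make `ν = 0` or
  `γ = 0` silently stop the head from training at all.
- **Discriminator saturation**: with strong batch effects a linear batch
  discriminator quickly becomes perfectly confident, its CE gradient
  vanishes, and the adversarial pressure on the encoder dies — gradient
  *ascent* on a saturated discriminator relocates clusters rather than
  overlapping them, and Adam's per-parameter normalization makes very
  large `γ` behave identically to moderate `γ`. Dropout on the
  discriminator input (the spec for the heads) is our mitigation: it
  keeps the discriminator imperfect and the gradient alive. It does not
  make the GRL merge fully separated clusters on its own; see
  "Limitations".
- **Min–max clamp** (batch-mapping strategy): the composite
  `rec + ν·classif + β·KLD − γ·disc` can go negative when the
  discriminator loss grows; a negative objective must not drive updates,
  so the step is skipped (gradients zeroed) when the clamp engages.
- **VAE stability**: `log σ²` is clamped to ±10 with gradient masking
  outside the interval.
- **Zero-variance features** under standard/robust scaling are set to 0
  with a warning instead of dividing by zero (common for features that
  are entirely missing within one batch).
- **Robust scaling**: 25th/75th percentiles with linear interpolation
  (R quantile type 7).
- **Checkpoints** store parameters as C99 hex-float literals in JSON, so
  a save/load round trip is bitwise exact and still plain text.
- **Determinism**: every stochastic step (initialization, dropout,
  sampling, `ε`, triplet mining, splits, search) draws from seeds
  recorded in the configs; identical seeds give identical runs.

## Hyperparameter search

No Bayesian-optimization package is assumed: `hyperopt_search()` ships a
small density-ratio sampler (good/bad trial split at the top quartile,
candidates drawn around good values and scored by a kernel-density
ratio — the tree-of-Parzen-estimators idea) with pure random search as
the startup phase and as an explicit `sampler = "random"` fallback. The
objective is the unweighted mean of best validation MCC over holdout
repeats; conditional parameters (`margin`, `beta`, `gamma`) are sampled
only for families that use them. Default ranges are conventional spans:
learning rate and weight decay log-uniform over 1e-5–1e-2 and 1e-8–1e-2,
dropout 0–0.5, `layer1` 32–1024, `layer2` 16–256 (capped at `layer1`),
label smoothing 0–0.2, margin 0–10, `beta`/`gamma` log-uniform 1e-4–10.

## The synthetic world

`simulate_omics()` writes, on the log scale: a log-normal baseline per
feature; class effects of `class_effect_size` (in units of the noise sd)
on a random 10% of features; per-batch per-feature additive offsets
(`batch_additive_sd`) and multiplicative factors
(log-sd `batch_multiplicative_sd`) — additive on the log scale is
multiplicative on intensities, the usual LC-MS drift model; optionally a
per-batch monotone cubic warp (a distortion linear corrections cannot
undo); Gaussian noise; then `expm1`, flooring at 0, and uniform
zero-coding of `missing_rate` entries. QC samples are the global mean
profile plus the batch effect and noise. Defaults (6 batches × 40
samples, 200 features, 2 balanced classes, unit noise) mirror a
mid-sized discovery cohort.

What it does **not** emulate: intensity-dependent missingness (real
non-detections censor low intensities; here the mask is uniform),
correlated feature blocks (peptides of one protein), retention-time
drift within a run, heteroscedastic noise, or batch × class confounding.
A green test on this world therefore establishes that the machinery
optimizes what it claims and recovers planted structure — not that any
model will win on a particular real cohort.

## Limitations

- The GRL adversarial strategy cannot, by itself, merge batch clusters
  that are *fully separated* and that reconstruction actively needs to
  keep apart; in that regime the per-batch normalization variants carry
  most of the correction and the adversarial term handles the residual
  structure. The integration test reflects this: its AE-DANN
  configuration uses `standard_per_batch` preprocessing, exactly as a
  hyperparameter search over the six variants would select.
- The reversed-triplet strategy follows a plain-language description
  rather than printed equations (standard batch triplet loss behind the
  GRL); it is labeled as such. Likewise, the batch-mapping adversarial
  models place their discriminator on `z` (symmetric with the DANN
  variant), one of two defensible readings.
- Pure-R training is practical up to a few thousand samples and a few
  thousand features on one CPU; beyond that, a tensor library is the
  right tool.
- Warmup is transductive by default (see "Protocol"); users comparing
  against strictly inductive pipelines must opt into the leakage-free
  mode.
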