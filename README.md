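# neurofuse

Multimodal fusion of structural MRI and resting-state MEG for early
Alzheimer's / mild-cognitive-impairment (MCI) classification, implemented as
a self-contained R package: two modality-specific convolutional feature
extractors, a spatial-channel cross-attention fusion (SCCAF) module, three
fusion strategies (early / intermediate / late), a full training and
cross-validated evaluation protocol, band-wise MEG spectral analysis, model
complexity accounting, and a synthetic cohort generator that emulates a
two-site MEG+MRI dementia cohort.

## Who this is for

Researchers studying *where* multimodal neuroimaging pipelines should fuse —
at the input, the feature level, or the decision level — and methodologists
who want a fully inspectable CPU implementation of cross-modal attention
fusion: every layer (convolution, per-sample normalisation, adaptive pooling,
attention, channel-wise aggregation) carries a hand-derived backward pass
that is finite-difference-tested, so the package doubles as a reference
implementation.

## The model

Each subject contributes a MEG magnetometer segment (102 sensors x 8192
samples at 500 Hz) and a registered T1 volume (192 x 192 x 182 voxels,
zero-padded to 192^3).  A 2D branch (a (1, 15) temporal strip-convolution
stem, then residual blocks striding only time) maps MEG to features of shape
(C, 102, 128); a 3D branch (7^3 stem, isotropic residual blocks) maps the
volume to (C, 24, 24, 24).  The SCCAF module fuses them:

* **MMPE** — adaptive average pooling to (64, 64) and (16, 16, 16), so both
  modalities yield P = 64 x 64 = 16^3 = 4096 tokens; flattening, a
  per-channel depth-wise projection, and a learned positional embedding give
  token matrices `F_meg, F_mri in R^(P x C)`.
* **SCA** — cross-modal scaled dot-product attention with queries from the
  opposite modality:
  `Z_a = softmax(Q_b K_a' / sqrt(C)) V_a`, `Z_b = softmax(Q_a K_b' / sqrt(C)) V_b`.
* **CFA** — an MLP on `[Z_a, Z_b]` and a pairwise softmax produce convex
  per-token per-channel weights, `F_fused = w_a * F_meg + w_b * F_mri` with
  `w_a + w_b = 1`.

Training minimises softmax cross-entropy `L = sum_x p(x) log(1/q(x))` with
Adam (lr 0.001, batch 2, weight decay 1e-4, 100 epochs) under stratified
5-fold cross-validation; evaluation reports accuracy, F1,
sensitivity/specificity, MCC, ROC/AUC and PR/AP, with paired
Bonferroni-corrected t tests between strategies.

## Worked example

Generate a small synthetic cohort in which the class signal is split across
modalities (structural effect d = 1 in a fixed region, 1.6x MEG high-gamma
power), train the intermediate-fusion model, and evaluate:

```r
library(neurofuse)

ds  <- benchmark_dataset("complementary", n_per_group = 150, seed = 11)
cfg <- benchmark_train_config(epochs = 8, seed = 11)

fit <- nf_train(ds, "inter", benchmark_model_config("inter"), cfg)
fit
#> <nf_model> strategy: inter (fitted)
#>   inputs: MEG 8x256 | MRI 16x16x16
#>   channels: 8 | parameters: 25,610
#>   final epoch mean loss: 0.001453

pr  <- predict(fit, ds, type = "prob")
met <- score_metrics(pr[, "MCI"], ds$cohort$group == "MCI")
round(unlist(met[c("acc", "f1", "mcc", "auc")]), 3)
#>  acc   f1  mcc  auc
#>    1    1    1    1
```

Those are training-set numbers — the fitted network separates subjects it
has seen perfectly, which mostly tells you the optimiser works.  The honest
figure is the cross-validated comparison that `run_experiment()` (and the
acceptance script) computes on held-out folds; at this reduced scale it
gives mean validation accuracies of about 0.76 (InterFusion), 0.76
(MEG-only) and 0.80 (MRI-only) — fusion matches the weaker modality and
trails the stronger one, a scale limitation the methods vignette analyses
in detail.  `summary(fit)` breaks parameters down by layer kind;
`plot(fit)` draws the loss trace; `complexity_table()` reproduces the
parameter/FLOP ordering of the strategies (early < inter < late).

A command-line interface over the same functions lives at
`inst/cli/neurofuse.R` (`simulate`, `bands`, `train`, `evaluate`, `compare`,
`complexity`).

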