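---
title: "Sequential learning with experience replay: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential learning with experience replay: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Prognosis models — "will this patient's disease worsen within a fixed
horizon?" — are starved for data, because longitudinal outcomes are far
scarcer than cross-sectional diagnostic labels. A common remedy is to
pretrain on a large diagnosis cohort (ordinal severity grading of single
images) and then fine-tune on the small prognosis cohort. The catch is
catastrophic forgetting: after fine-tuning, the model's diagnostic accuracy
collapses, particularly on rare severity grades, which matters whenever the
deployed model is expected to keep serving both tasks.

`seqreplay` is a desk-scale harness for studying this trade-off end to end.
It implements six training regimes for one two-headed convolutional
network:

* **diagnosis reference** — trained on the diagnosis cohort only; both the
  dedicated comparator and the pretrained initialization;
* **single-task prognosis** — from random or diagnosis-pretrained weights;
* **single-cohort multitask** — both heads, prognosis-cohort data only,
  random initialization;
* **diagnosis-pretrained multitask** — same data regime, pretrained
  initialization, no replay;
* **concurrent multitask** — both cohorts via per-batch task sampling,
  random initialization;
* **sequential learning with experience replay** — pretrained
  initialization, then prognosis training with diagnosis batches
  interleaved at probability 0.5.

Every batch is single-task except in the two single-cohort multitask
regimes, where each batch contributes both its grade and its progression
label (summed unweighted — the sampling probability, not a loss
coefficient, balances the tasks).

## The synthetic world

No real radiographs are used. The generator emulates the statistical
structure such studies share:

* Each patient carries two standard-normal latents: severity $s$ and a
  progression rate $r$, correlated at $\rho$ (default 0.6).
* The ordinal grade of a scan is $s$ thresholded at fixed cutpoints. The
  default cutpoints place the class priors at (0.35, 0.30, 0.20, 0.12,
  0.03): imbalanced, with a rare maximal grade so that rare-class
  forgetting is observable.
* The binary progression outcome is Bernoulli with logit
  $\alpha + \beta_s s + \beta_r r$, drawn once per patient and attached to
  all of that patient's prognosis-cohort scans. The prognostic signal is
  therefore correlated with, but not determined by, baseline severity.
* A patient-level subset (default 20%) forms the prognosis cohort, and
  scans at the maximal grade are excluded from it — the analog of
  excluding end-stage disease at baseline. Because the prognosis cohort
  therefore contains no maximal-grade scans, regimes that fine-tune on it
  alone *must* forget that grade; this is the designed forgetting
  mechanism, mirroring the real-world one.
* Images (64 px, grayscale) carry severity through the gap width between
  two bright horizontal bands (a joint-space-narrowing analog) and a
  Poisson count of bright spots (an osteophyte analog); they carry the
  progression rate *only* through a random-phase intensity ripple along
  the bands. Setting `texture_amplitude_coef = 0` removes the
  prognosis-specific channel entirely, which gives a clean identifiability
  test: under ablation no estimator can beat the severity-only oracle.
* Grades are non-decreasing over visits: scan severity at visit $v$ is
  $s + \delta\,v\,\max(r, 0)$, and the follow-up grade used for subgroup
  assignment re-thresholds after `followup_visits` more units of drift.

Closed-form calibration: the Bayes score for the outcome is
$\eta = \alpha + \beta_s s + \beta_r r$, normal with variance
$\beta_s^2 + \beta_r^2 + 2\rho\beta_s\beta_r$, and
`oracle_auroc_closed_form()` integrates the positive-class density of any
such score against its negative-class CDF. The defaults put the full
oracle at about 0.83 — learnable but imperfect — with a severity-only
ceiling near 0.76, so roughly seven AUROC points are genuinely carried by
the texture channel.

What a green test does **not** establish: the images are caricatures
(three signals, no anatomy, no scanner effects), the network is tiny, and
cohort sizes are two orders of magnitude below the real studies. The
harness reproduces *mechanisms* (pretraining transfer, forgetting, replay
rescue), not any real-data effect size.

## Leakage-safe evaluation protocol

Patients — never scans — are the unit of splitting. The prognosis cohort
is partitioned into 5 folds; per fold the test fold is held out, the next
fold (cyclically) is validation, the remaining three train. The
diagnosis-pretraining set for a fold is every diagnosis-cohort patient
*except that fold's test patients* (the pretraining test-set holdout), so
evaluation patients are unseen by the entire pipeline. The design this
follows states the holdout for the test set only; this package excludes
each fold's validation patients from pretraining as well — strictly more
conservative, and it lets the forgetting analysis evaluate on both the
validation and test patients' graded scans, doubling its support.
An audit log records every scan id each training stage touches, and
`leakage_audit()` replays it against the split plan; the test suite
asserts zero violations over the full default experiment.

Metrics follow the standard protocol: AUROC/AUPRC per fold, operating
points chosen by maximizing the Youden index on the fold's validation set
and transferred to its test set, mean ± sd over folds (sample sd, n−1),
out-of-fold predictions pooled for ensembled ROC curves, DeLong's test
(two-sided, placement-value covariance) for pre-registered strategy
pairs, balanced accuracy / macro / micro AUROC and confusion matrices for
the diagnosis task, and subgroup AUROCs for the incidence-like (baseline
grade 0–1) and progression-like (grade 2–3) strata.

## Numerical and design choices

Choices the underlying design left open, and how this package resolves
them:

* **Backbone.** Three 3×3 stride-2 convolution blocks (8→24→48 channels),
  global average pooling, 64-d embedding. Strided convolution replaces
  conv-plus-pooling: four times cheaper at equal downsampling, which is
  what keeps the full benchmark inside a CPU budget. Grades are nominal
  classes under (optionally inverse-frequency weighted) cross-entropy;
  the prognosis head is a single sigmoid logit.
* **Precision.** All trunk arithmetic runs in single precision (one GEMM
  per layer against an im2col matrix); the R boundary stays double. The
  unit tests validate the kernels against a pure-R double-precision
  reference forward pass, because finite differences taken through the
  float path are dominated by ReLU-crossing and rounding noise. At package
  load the BLAS is pinned to one thread (a no-op for non-OpenBLAS builds),
  so training trajectories do not depend on the host's core count.
* **Replay bookkeeping.** A replay epoch covers
  `train_config(replay_epoch_passes = 2)` shuffled passes of the prognosis
  training set — replay training processes both cohorts, so its epoch is
  sized to the combined workload; before each prognosis batch, diagnosis
  replay batches are drawn (from a cycling shuffled pool) while a
  Bernoulli(replay probability) coin keeps coming up "replay". With
  replay probability 0 this reduces *exactly* to single-task prognosis
  training, which the tests assert parameter-for-parameter.
* **Minimum steps per epoch.** At desk scale a prognosis "epoch" is only a
  few batches, so `train_config(min_steps_per_epoch = 4)` recycles the
  shuffled pool up to six optimizer steps per epoch. Without this floor a
  20-epoch run makes too few updates to train from random initialization
  at all.
* **Phase-1 → phase-2 transfer.** Trunk and diagnosis head are copied;
  the prognosis head is freshly initialized (preserves maximal diagnosis
  knowledge for replay).
* **Checkpointing.** The diagnosis reference checkpoints on validation
  balanced accuracy; every prognosis-bearing regime checkpoints on
  validation prognosis AUROC (falling back to validation loss, with a
  warning, when the validation fold is single-class). Ties break to the
  earliest epoch; non-finite entries are skipped with a warning. Loss
  criteria are minimized, AUROC/accuracy criteria maximized. Because the
  per-fold prognosis validation set is small, the phase-1 model instead
  validates on a dedicated 15% carve-out of the diagnosis-only patients —
  they sit inside every fold's pretraining holdout, so this costs no
  test-set integrity and stabilizes checkpoint selection considerably.
* **Early stopping.** Patience of 10 epochs on the checkpoint criterion.
* **Warmup.** The cosine schedule starts with a 2-epoch linear warmup.
  This matters most when fine-tuning from pretrained weights: without it,
  the freshly initialized prognosis head's first gradients arrive at the
  peak learning rate and disturb the trunk before any replay batch can
  consolidate it.
* **Augmentation.** Horizontal flip (p = 0.5), rotation within ±10°,
  random crop to 90% with nearest-neighbour resize, small shifts — applied
  to training batches only.
* **Seeds.** One experiment seed drives everything; per-stage seeds are
  derived by hashing a stage tag, so adding a strategy never perturbs
  another's randomness, and two runs of the same configuration agree
  byte-for-byte. All random draws happen on the R side (the C++ kernels
  are deterministic), in named substreams (initialization, data order,
  task sampling, augmentation).
* **Operating points.** The decision rule is score ≥ threshold ⇒
  positive; Youden ties resolve to the smallest maximizing threshold.
* **Macro AUROC** skips classes absent from the evaluation labels with a
  warning rather than erroring; **DeLong** returns p = 1 with a warning
  for identical curves and errors on degenerate variance with unequal
  AUROCs; the reported `n` counts evaluation units (scans), not patients.
* **Ensembling** averages probabilities, not logits. In cross-validation
  each scan is scored by exactly one fold's model, so pooling equals the
  general average-of-available-models rule.
* **No multiple-testing correction** across the registered DeLong pairs.
* **Generator defaults** were calibrated once — so that the diagnosis
  task is reliably learnable by the reference model, the closed-form
  prognosis oracle sits in the 0.75–0.90 band, and the forgetting regime
  is exhibited — and then frozen (the recorded replicate seeds are 1, 2,
  3). They are stated in `generator_config()`'s signature and are not
  adjusted by any test.

## Known limitations

* Single 2D grayscale modality; the multi-view and volumetric settings of
  real studies are out of scope.
* Balanced accuracy on the rare maximal grade rests on few test scans
  even after pooling folds, so per-seed forgetting deltas carry
  non-trivial Monte-Carlo noise; the acceptance checks therefore require
  their inequalities in a majority of replicate seeds, not in every seed.
* **A desk-scale asymmetry in the forgetting comparison.** The dedicated
  diagnosis reference selects, by construction, its best-balanced-accuracy
  epoch out of twenty; at this cohort size that statistic's per-epoch
  noise hands the reference a pure selection advantage of roughly ten
  points (measured: checkpoint 0.77 vs final-epoch 0.63 on an
  instrumented fold). The replay model checkpoints on validation
  prognosis AUROC — the protocol's deliberate choice — and so receives an
  unselected draw of the same distribution. Consequently the replay
  model's balanced accuracy reliably beats every other fine-tuned regime
  and keeps the rare grade the others lose, but it sits 8–20 points below
  the reference rather than matching it as it does at full scale, where
  per-epoch balanced accuracy is stable and the selection advantage
  vanishes. Raising replay volume (up to sixteen effective passes of the
  diagnosis pool), changing the learning rate over 5e-4–2e-3, warmup,
  unweighted cross-entropy and up to 3.8× trunk capacity were all probed
  before freezing; none closes this gap without breaking another property.
  The corresponding acceptance check is left failing, deliberately, with
  this analysis.
* Likewise, concurrent multitask training from random initialization
  cannot reach near-reference diagnosis skill with only a few effective
  passes of the diagnosis cohort, so the full-scale retention ordering
  (replay ≥ concurrent ≥ pretrained-no-replay) holds only in its outer
  links here.
* The experiment runner is deliberately single-threaded for bit
  reproducibility; wall-clock time scales linearly with cohort size,
  epochs and strategies.
* End-stage ("total joint replacement"-like) events are not modelled
  separately; the maximal-grade exclusion subsumes them.
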