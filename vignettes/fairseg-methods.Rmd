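---
title: "Fairness-aware curriculum and federated training for segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fairness-aware curriculum and federated training for segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fairseg)
```

## The problem

Deep segmentation models for musculoskeletal radiographs can reach high
average accuracy while performing systematically worse for some demographic
subgroups — a serious concern when the masks feed surgical planning or
disease monitoring. `fairseg` implements a family of training-side
interventions for this problem and a simulator to study them:

* **curriculum schedulers** that control the order and pace at which samples
  of different difficulty reach the optimizer,
* **progressive loss functions** that smoothly shift optimization emphasis
  from easy to hard samples over the course of training, and
* **federated aggregation rules** for multi-site training where each site
  keeps its data private and only model parameters are exchanged, including
  two rules that weight client contributions by local segmentation quality
  and one that additionally prunes anomalous clients.

Because real multi-site radiograph collections cannot be bundled, the
package ships a synthetic generator whose demographic and site structure
replicates a real two-cohort setting (761 hip and 707 knee patients over
five acquisition sites, see `demographic_table()`), and whose appearance
model induces a controllable subgroup disparity.

## Accuracy and fairness metrics

Segmentation accuracy is the multi-class intersection-over-union: for each
foreground class present in either mask, the ratio of the pixel intersection
to the pixel union of the binarized masks, macro-averaged over classes
(`iou_multiclass()`). A mask pair with no foreground anywhere scores 1 by
convention: predicting "nothing" where there is nothing is exactly right.

Subgroup fairness is summarized over the four race-gender groups
(White/Black x Male/Female), the finest partition the metadata supports:

* **Skewed error ratio (SER)** — the ratio of the largest to the smallest
  group error rate, `max_g(1 - IoU_g) / min_g(1 - IoU_g)`; 1 means no skew.
  The denominator is clamped at `1e-6` so a group at IoU 1 does not divide
  by zero; a single group yields 1 by convention.
* **Min-max disparity (MMD)** — the absolute range `max_g IoU_g - min_g
  IoU_g` of the group means; 0 means parity.
* **IoU SD** — reported as the *population* standard deviation over the four
  race-gender group mean IoUs, i.e. a group-level, not sample-level, spread.
  The magnitudes this produces are consistent with MMD (for four groups,
  SD is always at most MMD); a sample-level interpretation would give much
  larger values. `fairness_report()` implements this choice.
* **R&G mean SER** — the arithmetic mean of the race-wise SER (two groups:
  White vs Black) and the gender-wise SER (Male vs Female). The combination
  of the two one-attribute SERs into one column is a reporting choice of
  this package; the two components are also returned separately.

Pairwise configuration comparisons use a two-tailed paired t-test on
per-sample IoU aligned by sample id (`paired_iou_test()`), with the textbook
closed form (sample SD, n-1 degrees of freedom) and the convention that
zero-variance differences give p = 1 when the mean difference is 0 and p = 0
otherwise. Significance is read at p < 0.05 and no multiple-testing
correction is applied, matching common practice for this kind of
configuration table.

## Curriculum schedulers

All curricula use the model's own per-sample IoU as the difficulty proxy —
easy samples are the ones the model already segments well — and all but the
plain baseline interleave demographics: a round-robin over the four
race-gender groups in a fixed canonical order, so that every window of four
consecutive positions touches all groups until one exhausts.

* **base** — fresh uniform shuffle each epoch.
* **ri** (random interleaved) — demographic round-robin, random within
  group.
* **scl** (self-paced) — epoch 1 is randomly interleaved; from epoch 2 each
  group's stream is sorted easiest-first by the previous epoch's IoU.
* **tcl** (teacher-student) — ease is the negated gap between a frozen,
  fully trained teacher's IoU and the student's previous-epoch IoU. The gap
  is recomputed every epoch, so difficulty tracks the evolving student; a
  student that overtakes the teacher on a sample (negative gap) makes that
  sample "easier than converged", which the signed convention handles
  naturally. The teacher stays frozen for the whole run.
* **bcl** (balanced) — training starts from a demographically balanced
  random subset holding 20% of the training data (equal per-group quotas,
  largest-remainder rounding, ties broken by canonical group order) and
  grows to the full set by the final epoch. Growth is linear in the epoch
  index — the description of the procedure fixes only the 20% start and the
  full-set end, and linear is the least-committal interpolation. Admission
  from the unseen pool stays demographically balanced, mirroring the start:
  the new slots are shared equally among groups with pool samples and each
  group's quota is filled easiest-first, scored by a gradient-free forward
  pass. (Globally easiest-first admission is available by omitting the
  group map, but when difficulty correlates with group membership it defers
  the entire disadvantaged group to the final epochs, defeating the
  curriculum's balanced-exposure goal.) The epoch's active set is then
  re-sorted easiest-first in a single joint ranking (veterans by their
  previous-epoch IoU, fresh admissions by their admission score) and
  interleaved by group. Each epoch keeps the full-epoch optimizer budget by
  cycling the active subset up to one pass worth of steps — this decouples
  the curriculum's *ordering* effect from the confound of simply taking
  fewer optimizer steps, which otherwise dominates at small problem
  sizes.

Ties in ease are always broken by lexicographic sample id, so every order is
reproducible bit-for-bit. Each `CurriculumOrder` is a permutation of its
active set; property tests assert this on randomized inputs.

## Progressive losses

The progressive term modulates the standard pixelwise cross-entropy using
the per-sample performance deviation `dP_i = IoU_i - IoU_mean` (the sample's
most recent IoU against the previous epoch's mean; epoch 1 trains on the
plain loss). A weight `w` sweeps linearly from `+alpha` at the first
optimizer step to `-alpha` at the last, so emphasis moves from
over-performing (easy) samples early to under-performing (hard) samples
late. Per-step (rather than per-epoch) interpolation makes the sweep smooth
within epochs. `alpha` defaults to 1 and is configurable; nothing in the
procedure pins its value.

Two variants differ in where the rectification sits:

* **selective (SPL)**: `L = L_standard + w * sum_i max(dP_i, 0)` — only
  over-performers ever enter the term; negative `w` turns their contribution
  into a bonus.
* **tiered (TPL)**: `L = L_standard + sum_i max(w * dP_i, 0)` — with
  `w > 0` over-performers contribute, with `w < 0` *under*-performers do,
  which is the behavior that matches the intended "hard samples dominate
  late training".

Taken literally with hard per-sample IoU, these extra terms are constants
with no gradient. Two gradient semantics are therefore provided:

* `mode = "reweight"` (default): the per-sample loss is scaled by
  `1 + w * max(dP_i, 0)` (selective) or `1 + max(w * dP_i, 0)` (tiered),
  with `dP_i` fully detached and multipliers floored at 0 so the objective
  stays a non-negative combination of losses. This matches the narrative
  reading — gradients from easy samples are amplified early, hard samples
  late.
* `mode = "additive"`: the literal formula, with `dP_i` made differentiable
  through a soft IoU surrogate (`soft_iou()`, the probabilistic relaxation
  `sum(p y) / sum(p + y - p y)` per class) and the epoch-mean reference
  detached. This preserves formula fidelity at the cost of a gradient that
  *rewards* lowering the score of over-performers when `w > 0`.

The population sum over all `N` samples is estimated per batch and
normalized by batch size, making the term invariant to batching. At `w = 0`
both variants and both modes return the standard loss exactly, with
identical gradients — an invariant the test suite checks against the
compiled gradient path.

## The backbone and its optimization

The built-in backbone is a compact U-Net: one 3x3 convolution per stage
with leaky ReLU (slope 0.1), 2x2 max pooling between the three encoder
stages, nearest-neighbour upsampling with skip concatenation in the
decoder, and a 1x1 output convolution; 8 base channels doubling per stage,
about 15k parameters at the default configuration. The sizing is a
deliberate CPU-scale choice: the package's subject matter is the training
and aggregation machinery, not backbone capacity, and the model interface
(`build_model()` / `model_forward()` / flat parameter vectors, plus
function-valued predictors in `evaluate_model()`) lets larger backbones be
plugged in. Leaky rather than plain ReLU matters at this scale: with hard
rectification, small networks without normalization layers intermittently
collapsed into the all-background local optimum depending on the seed.

Forward and backward passes are hand-written (im2col + GEMM) in
RcppArmadillo and verified against central finite differences to relative
error below `1e-5` in the tests, for the cross-entropy path and the
soft-IoU penalty path separately. Optimization is Adam (`beta1 = 0.9`,
`beta2 = 0.999`) with coupled L2 weight decay. Defaults: learning rate
0.01, batch size 2, weight decay `1e-6`; the validated hyperparameter
ranges are lr in `[1e-4, 0.01]`, weight decay in `[1e-8, 1e-3]` and epochs
in `[25, 200]` (liftable with `allow_any_epochs` for small studies). The
small default batch gives the optimizer enough steps to converge at the
problem sizes below; per-sample cross-entropy is the mean over pixels, and
per-sample IoU for the curricula is recorded by one extra gradient-free
pass after each epoch.

## Federated simulation

`fairseg_federate()` partitions the non-test samples by acquisition site,
holds out a stratified 10% of each client's data as a local validation
split, and runs global rounds of broadcast - local training - aggregation.
Six aggregation rules are provided; all weight vectors are normalized to
sum to 1, so every global update is a coordinate-wise convex combination of
client parameters:

| strategy | client weight | extras |
|---|---|---|
| `fedavg` | local sample count `n_k` | — |
| `fedprox` | `n_k` | proximal pull `mu/2 * ||theta - theta_global||^2` during local steps |
| `feddp` | `n_k` | Gaussian noise `N(0, sigma^2)` added per parameter before transmission |
| `feddpfair` | `1 / SER_k` | DP noise as in `feddp` |
| `fediou` | local mean IoU | — |
| `fediou_outlier` | local mean IoU | clients with `IoU_k < Q1 - 1.5 IQR` excluded this round |

`IoU_k` and `SER_k` are computed on the client's local validation split —
the procedure being modelled does not say which data the client scores use,
and a held-out local split is the choice that avoids rewarding local
overfitting. `SER_k` is the R&G mean SER over the groups present locally; a
single-group client scores 1 (maximal weight under `1/SER`), which is
flagged as a modelling convention. For the DP-fair rule, noise is applied
to the parameters after local training and the (pre-noise) local scores
drive the weights. Quartiles use linear interpolation between closest ranks
(R's type 7), which reproduces the standard worked examples of the
`Q1 - 1.5 IQR` rule. Exclusion is per-round only: pruned clients receive
the next broadcast and keep training. Defaults: 20 rounds, 1 local epoch,
`mu = 0.01`, `sigma = 0.001` (well inside the explored 1e-5..0.1 noise
range); all configurable.

Degeneracies are exact and tested: `sigma = 0` makes the DP variants
reproduce their noiseless counterparts round for round; `mu = 0` makes the
proximal variant reproduce plain local training; a single-client federation
equals centralized training of that client under the same seeds.

## The synthetic generator

Each sample is a grayscale image with three left/right pairs of soft
elliptical structures over a darker background — a geometric stand-in for
paired anatomy (femur, acetabulum, patella) rather than a rendering of it.
Each of the six structure classes has a distinct mean radiodensity, and the
background carries a mild lateral intensity gradient; both provide the
positional and photometric cues that let a translation-equivariant network
separate left from right, as laterality markers and anatomic asymmetry do
in real radiographs. Difficulty has two axes:

* a **group-level appearance shift** — per race-gender noise SD (defaults
  0.04 / 0.06 / 0.12 / 0.16 for White-Male / White-Female / Black-Male /
  Black-Female) and contrast (1.0 / 1.0 / 0.90 / 0.85) — which induces the
  baseline subgroup disparity the mitigation methods are evaluated against;
* a **per-sample jitter** (uniform +/-25% on the noise SD) giving curricula
  a within-group difficulty signal.

These defaults are calibrated so that a plainly trained baseline shows a
clear disparity (R&G mean SER well above 1.2) while the disadvantaged
groups remain *learnable-but-behind* — the regime the mitigation methods
address, and the regime of the clinical segmentation setting this emulates,
where even the worst group sits at high IoU. Substantially harsher noise
makes the noisy groups' difficulty irreducible, at which point late-stage
hard-sample emphasis buys only noise. These are the package's standing
study conditions, not tuning knobs. In fixture mode the generator reproduces the bundled hip/knee
demographic tables cell for cell, including the strongly non-IID site
mixes (site A dominated by Black female patients, sites B/C by White
patients).

What the generator does **not** emulate: anatomical shape variation,
occlusion and overlap of structures, acquisition artifacts, scanner- or
site-dependent appearance (sites differ only in demographic mix), label
noise, and any correlation between demographics and anatomy beyond the
imposed appearance shift. A passing benchmark therefore demonstrates that
the schedulers, losses and aggregation rules behave as designed under a
controlled disparity — not that they would close real clinical gaps.

## Numerical choices

* All randomness flows from one master seed through named sub-streams
  (`substream_seed()`), so generation, splitting, site assignment, epoch
  shuffles, DP noise and per-round client training can be re-seeded
  independently and every run is exactly reproducible.
* Split and quota rounding is largest-remainder, ties by position /
  canonical group order; the balanced-curriculum growth target uses a
  `1e-9` tolerance inside the ceiling to keep exact-fraction epochs stable
  against floating-point error.
* He initialization, biases at zero; deterministic given the seed.
* Masks are stored as 8-bit PNG holding raw label values (lossless);
  images are 8-bit quantized.

## Problem sizes

The shipped study sizes are deliberate: the disparity benchmark uses 200
samples at 96x96 for 15 epochs (enough for the baseline disparity and its
mitigation to be visible, and the baseline to exceed IoU 0.5), and the
robustness study uses a five-site federation of 150 samples at 48x48 with
a centrally warmed start (12 epochs, so honest clients hold informative
local validation scores), three rounds of two local epochs, and one
anomalous client submitting random parameters. Unit tests run on 16x16
images with 2-channel backbones.

## Known limitations

* At short training schedules the progressive weight reaches `-alpha` at
  the very end of training, so the hard-sample-emphasis phase has no
  recovery time; on the shipped 15-epoch benchmark the tiered loss trades
  a noticeable amount of mean IoU for its (large) SER reduction. The
  accuracy-parity behavior reported for such losses elsewhere presumes
  long, converged schedules.
* The additive progressive mode optimizes a surrogate (soft IoU), so its
  penalty value and its gradient path refer to slightly different
  quantities; the default reweight mode avoids this at the cost of
  detaching the difficulty signal.
* No privacy accounting is implemented for the DP variants — noise is
  added exactly as specified, but no (epsilon, delta) budget is tracked,
  and no gradient clipping is applied.
* The federated simulator is sequential and single-process; stragglers,
  partial participation and transport are out of scope.
* IoU-based client weighting can in principle favor strong sites; the
  simulator reports per-round weights so such effects are inspectable.
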