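---
title: "Optimised class-imbalance correction for CT body-composition analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimised class-imbalance correction for CT body-composition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Body-composition analysis from abdominal CT rests on two steps that are
painful to automate: finding the axial slice at the third lumbar vertebra
(L3), whose tissue areas track whole-body composition, and segmenting that
slice into skeletal muscle (SM), subcutaneous adipose tissue (SAT) and
visceral adipose tissue (VAT). Both steps are dominated by *class
imbalance*: L3 slices are roughly 5% of an abdomen-and-pelvis series, and
each tissue occupies a small minority of the pixels in a slice. Models
trained naively on such data drift toward the majority class.

`ctbalance` implements an optimisation-incorporated training strategy in
which the two standard imbalance counter-measures are not fixed by hand
but exposed as *correction design variables* (CDVs) and optimised jointly
with the ordinary training hyperparameters:

* `d_a` — the **augmentation ratio**: the minority class is oversampled
  (rotation, horizontal/vertical flips) until its count reaches
  `round(d_a * n_majority)`. `d_a = 1` is exact 1:1 balance and is the
  *upper bound* of the search range, not a fixed setting: full balancing
  is often more augmentation than generalisation wants, and the optimiser
  is free to choose less. The lower bound is the raw class ratio (no
  augmentation). `d_a` applies to the detection task only; segmentation
  uses a fixed 4x augmentation of its (L3-only) training set.
* `d_c` — per-class **loss weights** in the weighted cross-entropy,
  bounded below by a task-specific minimum (next section).

The full design vector is `d = {d_h, d_a, d_c}` with `d_h` the
hyperparameter block: L2 regularisation and initial learning rate
(log-scale, `[1e-4, 1e-2]`), batch size (`[10, 32]`), gradient-norm
clipping threshold (`[1, 6]`), epochs (`[5, 20]`) and momentum
(`[0.7, 0.99]`). The objective minimised is the inverse F1 score of the
trained model on a held-out validation split,

    J(d) = (precision + recall) / (2 * precision * recall) = 1 / F1,

computed at slice level for detection (positive class = L3) and at pixel
level for segmentation, macro-averaged over the foreground classes
(SM, SAT, VAT, other) before inversion. Macro-averaging is a declared
choice (micro is available through `objective_from_counts(average =
"micro")`): it prevents the large "other" class from masking failure on
small tissues. A model with F1 = 0 gets a capped objective (`1e6` by
default) so the surrogate stays finite.

## Class-weight minima

Weight floors prevent the optimiser from silencing a class entirely:

* **Detection**: minimum weight `1/sqrt(f_k)` for class frequency `f_k` —
  the inverse-square-root rule, which up-weights the rare L3 class.
* **Segmentation**: minimum weight `f_k`, the ratio of the class's pixel
  count to the total. This rule gives *larger* floors to majority
  classes — the opposite of imbalance correction — but it is the rule as
  printed in the protocol this package implements, so it is the default,
  with `min_rule = "inverse_pixel_ratio"` available as the conventional
  alternative. We deliberately did not resolve this quietly: with the
  printed rule the baseline (weights pinned at the minima) is strongly
  background-biased, and the benefit of optimising `d_c` above the floor
  is correspondingly large.

Applied weights are `max(minimum_k, d_c_k)`, then rescaled to mean 1 so
that loss magnitudes are comparable across candidate weight vectors
during optimisation (the scale of a weighted loss is otherwise
confounded with its balance). The search range for each `d_c_k` is
`[m_k, 10 * max(m)]` — anchored, like the floors themselves, to the
class proportions of the training set; the factor 10 gives the optimiser
room to invert the weight ordering of the printed segmentation rule.

## Bayesian optimisation

`J(d)` costs a full training run per evaluation, so it is minimised with
a Gaussian-process surrogate and expected improvement (EI):

* mixed design space encoded to the unit cube (log variables via `log`,
  integers scaled continuously and decoded by rounding to the nearest
  feasible value);
* Matérn-5/2 kernel with per-dimension length-scales (ARD), kernel
  hyperparameters by marginal-likelihood maximisation with a fixed
  3-start L-BFGS-B multistart (deterministic, no RNG); observation-noise
  floor `1e-8`, jitter escalation if a Cholesky fails;
* EI in minimisation form, maximised over 2048 uniform cube samples plus
  local L-BFGS-B refinement from the best candidate;
* `n_init` space-filling initial designs from a Latin hypercube; the
  generic default is `min(max(5, 2d), floor(budget/2))`. Pipeline runs
  use an explicit `n_init` (8 at study scale) because CDV spaces have
  9–11 dimensions and `2d` would consume a small budget entirely;
* failed objective evaluations are caught, logged and recorded at the
  cap, and the loop continues.

All of these are conventional choices; every one is exposed as an
argument. The evaluation budget default is 40 generically and 20 in the
phantom-scale studies below.

During pipeline runs the objective is evaluated on a fixed inner
train/validation split of the *training* folds (default: 25% of training
patients, split at patient level). Test-fold data never influence design
selection.

## Reference backbones

Full-scale architectures (ResNet50-class detectors; U-Net, Swin-Unet or
SegFormer segmenters) plug in behind a two-function trainer contract:
`fit(images, labels_or_masks, design, weights, seed)` and
`predict(handle, images)`, with the requirement that the same seed and
inputs give identical predictions. The strategy being exercised is
backbone-agnostic, so the package ships two deliberately small reference
backbones that run on one CPU:

* `reference_detector()` — a residual CNN: 3x3 stem, two residual blocks
  with identity shortcuts, 2x2 max-pool between them, global average
  pooling, softmax head; default input 16x16, 4 base channels.
* `reference_segmenter()` — a three-level U-Net: 3x3 convolutions,
  max-pooling encoder, nearest-neighbour upsampling decoder with skip
  connections, 1x1 softmax head over the 5 class codes; default input
  32x32, 4 base channels.

Both are trained with SGD-with-momentum (the hyperparameter block names
momentum and a gradient threshold, which fixes the optimiser family) and
weighted cross-entropy; the global gradient norm is clipped at the
threshold before the momentum update, L2 decay applies to weights but
not biases, and per-step post-clip gradient norms and the optimizer step
count are recorded so tests can assert that every design variable is
consumed. Two numerical choices matter at this width: activations are
leaky ReLU (slope 0.1) and convolution biases start at 0.01, because
4-channel hard-ReLU networks can lose gradient flow at initialisation;
and all arithmetic is single precision, which is standard for CNN
training. Training is bit-reproducible for a fixed seed.

## Preprocessing and post-processing

* **HU window** `[-190, 150]`, implemented as clipping (saturation) —
  the standard CT windowing reading; rescaling instead of clipping would
  make the subsequent stretch redundant.
* **Histogram stretch** to `[0, 1]` with percentile endpoints (defaults
  1/99, configurable), applied per slice; a constant slice maps to
  zeros. The percentile parameters and the per-slice (rather than
  per-volume) scope are choices of this package — a per-volume flag
  would be a straightforward extension.
* **Resize**: bilinear for images, nearest-neighbour for masks (the only
  choice that preserves categorical labels); only downsizing is allowed,
  and resizing to the native size is an exact identity. Physical areas
  measured on a resized mask are corrected by `(native/current)^2` —
  factor 4 exactly for 512 to 256.
* **HU-range refinement** of predicted masks: a pixel predicted SM, SAT
  or VAT whose *original* HU value lies outside `[29, 150]`,
  `[-150, -50]` or `[-190, -30]` respectively is vetoed. Vetoed pixels
  go to "other" (code 4) by default rather than to another tissue: the
  SAT interval is a subset of the VAT interval, so range-based
  reassignment between the fat classes is ambiguous — spatial prediction
  is trusted for class choice and HU only vetoes. The alternative
  (`out_of_range = "nearest_valid"`) assigns the tissue whose interval
  contains the value. Refinement is idempotent and can only shrink
  tissue classes.

## The phantom generator

No public cohort exists for this protocol, so `generate_cohort()`
produces synthetic patients that reproduce the *statistical* structure
the method addresses, not anatomy:

* ~5% of slices per patient flagged L3 (contiguous block, at least one
  per patient; count = `round(l3_fraction * slices)`), giving the
  ~380-versus-11,000 imbalance regime at 150-patient scale;
* each slice an elliptical abdomen: outer SAT ring, SM band inside it,
  interior VAT blobs on an organ background, and a posterior vertebral
  bone feature whose transverse extent varies smoothly along the scan
  and is distinctly (2.2x) wider on L3 slices — a deterministic
  geometric signature a small classifier can learn;
* tissue HU drawn by rejection sampling from truncated normals inside
  the class ranges above (truncation rather than clipping, so tissue
  histograms carry no boundary spikes), acquisition noise folded into
  the per-class spread; organ HU overlaps the SM range, so intensity
  alone cannot segment the slice;
* bit-identical cohorts under a fixed seed; per-patient seeds derived
  from the master seed.

Defaults (64-pixel slices over a 384 mm field of view, 40 slices per
patient, SM/SAT/VAT means 50/-100/-90 HU with 15/18/25 HU spread, 10 HU
noise) were chosen once as plausible CT values. What passing tests on
phantoms do **not** show: performance on real anatomy, robustness to
scanner variation, partial-volume effects, or pathology — the phantom
has none of these. They do show that the optimisation loop, the
correction variables, the metrics and the protocol behave as specified
end-to-end.

## Study design used in the tests

The directional study (also the shape of `scripts/acceptance.R`) runs
both arms on one test fold of a phantom cohort:

* **with-CDV arm**: BO over `d_h + d_a + d_c`;
* **baseline arm**: the same BO over `d_h` only, with `d_a` pinned at
  the raw ratio (no augmentation) and `d_c` pinned at the minima — an
  ablation of the correction variables, not of optimisation itself
  (`baseline_mode = "none"` gives a fixed mid-range design instead).

Problem sizes were fixed in advance as the package's CPU-scale study
conditions: 40 patients x 40 slices at 64x64 (test suite; 24 patients
in the acceptance script), BO budget 20 with 8 initial designs (14/7 in
the script), detector input 16x16, segmenter input 32x32, three
replicate seeds. Expected direction: the with-CDV arm matches or beats
the baseline on mean absolute slice error and macro-Dice in most
replicates. At this scale the comparison is directional only — absolute
metric values depend on the phantom and the reduced backbones and are
not comparable to clinical-scale results.

## Evaluation battery

Per-patient L3 prediction takes the slice with the highest L3
probability (ties toward the lower index); the error is the signed
index difference to the nearest true L3 slice (the reference L3 run
spans several slices, so distance-to-run is the natural error).
Bland–Altman limits use the n-1 standard deviation and strict
inequalities for the within-limits fraction (an all-equal degenerate
case therefore reports 0). Segmentation reports one-vs-rest Jaccard,
Dice, sensitivity, specificity and mean surface distance (4-connected
boundaries; directed predicted-to-truth by default, symmetric
available; undefined — `NA` — when a boundary is empty, never 0), plus
physical areas with the squared resize correction and ordinary
regression R² between predicted and reference areas. Empty-vs-empty
classes score 1 by convention. Every metric is cross-checked in the
test suite against brute-force enumeration on random masks.

## Known limitations

* The phantom's L3 signature is a single geometric feature; real L3
  identification uses anatomical context the reference detector never
  sees.
* The reference backbones are orders of magnitude smaller than clinical
  models; conclusions transfer only directionally.
* The GP surrogate treats integer variables by continuous relaxation
  and rounding; a dedicated mixed-variable kernel may do better in
  larger budgets.
* The printed segmentation weight-minimum rule is kept as the default
  even though it handicaps the baseline; users wanting a conventional
  floor should set `min_rule = "inverse_pixel_ratio"`.
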