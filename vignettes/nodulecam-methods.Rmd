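---
title: "Volumetric nodule classification with Grad-CAM explanations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric nodule classification with Grad-CAM explanations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecam)
```

## The problem

Lung-cancer screening by low-dose CT produces large numbers of candidate
findings that must be sorted into nodules and non-nodules. A 2D network sees
one slice at a time and discards the out-of-plane context that distinguishes
a roughly spherical nodule from the tube-like cross-section of a vessel; a
3D convolutional network consumes the whole candidate volume. The second
obstacle to clinical use is opacity: a classifier that cannot show *where*
it found evidence will not earn a radiologist's trust. Gradient-weighted
class activation mapping (Grad-CAM) addresses that by projecting the
class-score gradient onto a convolutional layer's feature maps and rendering
the result as a saliency volume over the input.

`nodulecam` implements this pair — a lightweight 3D CNN classifier and
volumetric Grad-CAM — together with everything needed to exercise the
pipeline end to end at desk scale: declarative architecture descriptions
with a parameter-count audit, a synthetic nodule-phantom generator with
voxel-level ground truth, an Adam/cross-entropy training loop, confusion and
ROC/AUC evaluation, NIfTI/NRRD volume I/O, and a command-line interface.

## Architectures as auditable declarations

The three networks (a 2D AlexNet-style baseline, its 3D counterpart, and the
lightweight "proposed" 3D model) are reconstructed from their published
layer tables. Those tables print, per layer, an output shape and a parameter
count — but no kernel sizes, no padding modes, and (for the lightweight
model) a layer order with internal contradictions: a duplicated pooling row
with an impossible channel count, a dense row pasted in twice, and printed
shapes that cannot all hold simultaneously.

The reconstruction therefore treats the **parameter counts as the
authoritative machine-checkable facts**. For a biased N-dimensional
convolution the count `k^N * c_in * c_out + c_out` determines the kernel
edge uniquely; `derive_kernel_size()` inverts it by brute force over
`k = 1..11`. Two printed cells (18454 in the 2D table, 53328 in the 3D
table) admit no integer kernel; they are carried as *known typos* with
corrected values (18464 and 55328, both consistent with `k = 3` at the
printed channel transitions) rather than silently repaired or reproduced.
Padding is `"same"` where the printed shape is preserved and `"valid"`
elsewhere, and the lightweight model's final pooling stage collapses the
spatial extent to 1³ so that the flatten width is 64 — forced by the
16640-parameter dense layer that consumes it (`16640 = 64 * 256 + 256`).

`audit()` rebuilds a model and pairs every realized per-layer count with the
printed expectation; each layer reports `match`, `known-typo`, or
`mismatch`, and only a mismatch fails the audit:

```{r audit}
audit(build_model(canonical_description("alexnet3d"), seed = 1))
```

Batch normalization is counted at 4 parameters per channel (scale, shift,
running mean, running variance), as the published tables do; the running
pair is state, not trainable weight, and is excluded from optimization.

## The conv-net engine

No deep-learning framework is available to R in this project's dependency
set, so the package carries a compact volumetric engine in C++
(RcppArmadillo): convolutions via im2col + single-precision GEMM, max
pooling, batch normalization, dense layers, dropout, global average
pooling, and the full reverse-mode pass. 2D networks run through the same
code path as 3D networks with a degenerate z-axis. The engine's correctness
is established in the test suite by finite-difference gradient checks
(tight tolerances on ReLU-free networks, where central differences are
exact to float32 roundoff; direction and magnitude checks on kinked ones)
and by an independent direct-convolution oracle in R.

Numerical choices, all fixed and documented here:

* **Initialization.** The published protocol states only that random weights
  have "max values" of 1. Initializing uniformly on [−1, 1] is one reading,
  but it provably cannot train under the protocol's own optimizer settings:
  with Adam at learning rate 10⁻⁴ and the epoch budgets used here, weights
  move at most ~0.1 from their starting point, so an initial noise scale of
  0.58 in the classifier head dominates any learnable signal. The package
  instead draws from the fan-scaled uniform distribution with limit
  `min(1, sqrt(6 / (fan_in + fan_out)))` — every weight still has maximum
  magnitude 1, activations keep a stable scale at depth, and parameter
  counts (the audit surface) are unaffected. Biases start at zero,
  batch-norm at identity.
* **Activation order.** ReLU is applied at the producing layer's output
  (conv → ReLU → batch-norm). Grad-CAM taps therefore see post-ReLU,
  non-negative activations, the standard choice.
* **Batch normalization** uses biased batch variance during training,
  an exponential running average (momentum 0.9) for inference, and
  ε = 10⁻⁵.
* **Dropout** (rate 0.5 by default — the rate is never published) is active
  only during training, with masks drawn from a counter-based seed so
  training steps replay bit-identically.
* **Stability.** Softmax cross-entropy is computed in log-sum-exp form;
  scores of ±1000 produce exact zero loss rather than overflow.

## Grad-CAM and its oracle

For a target class `c` and a convolutional layer with feature maps `A^k`,
the map weight is the summed gradient of the pre-softmax class score,
`w_k = Σ_ij ∂y^c / ∂A^k_ij`, and the saliency is
`L = ReLU(Σ_k w_k A^k)`, upsampled trilinearly to the input grid and
min-max normalized. Three derivation-level facts become executable tests:

* On a network whose head is global average pooling followed by one dense
  layer, the dense weights of the target class *are* the map weights, so the
  class activation map (CAM) is available in closed form; Grad-CAM must
  reduce to it exactly. `cam_reference()` computes that closed form and the
  suite asserts equality of the normalized maps to 1e-5.
* Defining weights as gradient sums versus gradient means changes raw maps
  by the constant spatial size only; normalized maps are identical. Both
  modes are exposed and the equivalence is asserted directly.
* The gradient is taken on the pre-softmax score, so a network whose class
  score is constant in the input yields an exactly zero heatmap, and the
  trailing ReLU makes every heatmap non-negative.

Upsampling to input resolution is not a naive stretch: valid convolutions
and pooling both scale and shift the feature grid relative to the input, so
the package composes the exact affine receptive-field map (per-axis scale
and offset) through the layer stack and resamples along it. For the 10³
grid of this model that mapping is input-voxel `= 2·cell + 5`; a plain
linear stretch would misplace saliency by several voxels, more than a small
nodule's radius. An alignment unit test (a known bright spike recovered by
the heatmap argmax) pins the transform.

The default target layer is the last convolution (the finest semantic
grid), overridable by index. For *localization scoring* against phantom
ground truth the package's own evaluation uses the deepest conv layer with
at least 8 cells per axis (the 10³ grid here): the final 4³ grid has a cell
pitch of ~6.8 input voxels, which by construction undersamples nodules
whose radii start at 3 voxels, so an argmax-in-mask criterion would measure
grid geometry rather than model behavior there.

## The phantom generator

Real CT with expert annotations cannot ship with a package; the generator
stands in for it with the simplest geometry that preserves what the
pipeline needs: a binary task with a *spatially localized* ground truth.
Positive volumes contain one bright quasi-spherical nodule (axis-aligned
ellipsoid, per-axis radii drawn from 3–6 voxels, quadratic intensity
falloff) at a uniformly random interior position; both classes contain
vessel-like bright cylinders (random axis, radius 0.8–1.5 voxels) as
distractors; Gaussian noise is added on top of a flat background.
Structures combine by voxelwise maximum, as overlapping tissue of one
attenuation class would. Intensities are abstract floats standardized at
training time; no Hounsfield calibration is attempted.

Default geometry: 27³ voxels (the lightweight model's input; 32 for the
baselines), nodule contrast 1.0 against vessel contrast 0.6, noise standard
deviation 0.05, and 1–3 vessels per volume. The contrast gap is deliberate:
with zero noise the maximum-intensity statistic separates the classes
perfectly (`threshold_baseline()`), which makes trained-model tests
well-posed — a model that fails to learn the noise-free task indicates a
defect, not an unlucky dataset — and the same statistic degrades
monotonically as noise rises, which the suite asserts over a seed ensemble.
Because vessels appear equally in both classes, the only class-discriminative
structure is the nodule itself, so a trained model's saliency has a
meaningful target to hit.

What the phantoms deliberately do not model: lung anatomy, airway trees,
nodule texture classes (spiculation, ground-glass), scanner artifacts, HU
calibration, or annotation disagreement. Passing tests on phantoms
demonstrate that the architecture, optimizer, explanation machinery and
evaluation arithmetic are correct and that the pipeline can learn a
localized 3D discrimination — they say nothing about clinical performance
on patient data.

## Study design: split, train, validate once more, test once

`make_splits()` reproduces the holdout arithmetic of the study design: the
test set is carved out first (30% of all volumes), then 10% of the training
volumes become the validation set. On the balanced 2,000-volume design that
is 1,400 training volumes (140 of them validation) and 600 test volumes.
Assignment is stratified by label with largest-remainder rounding, keeping
every split's class balance within one sample of the global ratio.

Training follows the published protocol where it is stated — Adam with
learning rate 10⁻⁴, β₁ = 0.9, β₂ = 0.999, softmax cross-entropy — and makes
artifact choices where it is not: 50 epochs and batch 32 as generic
defaults, early stopping on validation loss (patience 10), the checkpoint
returned being the validation-loss minimizer (earliest epoch on ties).
Input volumes are standardized to zero mean and unit variance using
training-split statistics only. The API encodes the single-use test
discipline: `validate()` may be called freely inside the
design-train-validate iteration loop, while `evaluate_test()` records each
manifest it scores and warns when the same held-out split is evaluated a
second time.

## Evaluation

`confusion()` thresholds probabilities (a tie at the threshold counts
positive — the convention is a package choice, stated rather than implied),
and `metrics()` computes accuracy, precision, recall/sensitivity,
specificity, false-positive rate and F1 exactly by their contingency-table
formulas. A statistic with a zero denominator is reported as `NaN` and
listed in an `undefined` field; silently substituting 0 would let a
degenerate evaluation masquerade as a bad-but-valid one. `roc_auc()` sweeps
all observed thresholds and integrates trapezoidally; the suite checks it
against the exhaustive pairwise Mann–Whitney probability (ties counting
one half) at 1e-10 and against an independent ROC implementation.

## Desk-scale validation experiment

The package's own end-to-end claim, executed in the acceptance test, is
deliberately scaled to a desktop: noise-free phantoms, 400 volumes under
the holdout design above, the published optimizer settings, a
20-epoch budget (the returned checkpoint is the validation-loss
minimizer), and batch size 8 — sized so that the of order 250 effective
training volumes still yield enough optimizer steps per epoch — over three
independent seeds. Early stopping is deliberately *not* used here: with
only 28 validation volumes the validation loss is too noisy to serve as a
stopping signal, and patience-based stopping was observed to truncate
training at badly undertrained checkpoints. The medians over seeds of
held-out accuracy and AUC, and the fraction of true positives whose
Grad-CAM argmax falls inside the ground-truth nodule mask (scored at the
10³ conv grid), are the reported quantities.

A caution on the localization score: argmax-inside-mask is a strict,
all-or-nothing statistic. On these phantoms the trained models' saliency
concentrates on and around the nodule with no systematic offset, but it is
often partly annular — boundary-sensitive features are highly
discriminative — and retains secondary responses on vessels, so the single
brightest voxel can sit a voxel or two outside the hard ellipsoid mask or,
occasionally, on a distractor. The statistic is therefore substantially
more conservative than visual inspection of the overlays suggests, and
more conservative than mass-based localization summaries would be.

Published headline numbers on the real 888-scan CT corpus (97.17%
accuracy, AUC 0.97) are *not* reproducible from this package: they require
the external dataset and large-scale training, and no number printed by
this package should be read as a reproduction of them.

## Known limitations

* The engine is single-threaded CPU code tuned for these small volumes; it
  is not a general-purpose training framework (no GPU, no autograd beyond
  the implemented layers, no grouped convolutions or local response
  normalization from the original AlexNet lineage).
* Heatmap upsampling is trilinear; no interpolation scheme is published for
  the saliency maps, and other choices would shift argmax positions by at
  most a cell.
* The single-use test ledger is per-session and keyed by split assignment;
  it is a guard rail, not an enforcement mechanism.
* DICOM series input is out of scope; NIfTI/NRRD cover the tested surface.
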