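# nodulecam

Lightweight 3D convolutional networks with Grad-CAM visual explanations for
lung-nodule classification, in R.

CT screening for lung cancer produces candidate volumes that must be sorted
into nodules and non-nodules. A 3D CNN can use the full volumetric context a
2D slice classifier discards, and gradient-weighted class activation mapping
(Grad-CAM) can show *where* the network found its evidence — the property
that makes such a model auditable by a radiologist. `nodulecam` implements
both, plus everything required to run and test the pipeline at desk scale
without patient data:

* **Declarative architectures with a parameter audit.** Three networks — an
  AlexNet-style 2D baseline, its 3D counterpart, and a lightweight
  "proposed" 3D model (27³ input) — are reconstructed from their published
  layer tables. Kernel sizes are recovered by inverting the count formula
  `k^N·c_in·c_out + c_out`; `audit()` verifies every built layer against the
  printed counts and flags the two published cells that admit no integer
  kernel (18454 and 53328, corrected 18464 and 55328) as known typos.
* **A compact volumetric conv-net engine** (RcppArmadillo: im2col + sgemm
  convolutions, batch-norm, max/global-average pooling, dense, dropout,
  full backward pass) with Adam training on softmax cross-entropy —
  correctness pinned by finite-difference gradient checks and a
  direct-convolution oracle.
* **Volumetric Grad-CAM**, `L = ReLU(Σ_k w_k A^k)` with
  `w_k = Σ_ij ∂y^c/∂A^k_ij`, trilinearly upsampled and min-max normalized;
  on GAP + linear networks it reduces exactly to the closed-form CAM
  (`cam_reference()`), the module's built-in oracle.
* **A phantom generator**: bright quasi-spherical nodules with voxel-level
  ground-truth masks, vessel-like cylinder distractors in both classes,
  additive Gaussian noise, and bit-reproducible seeding.
* **Evaluation**: confusion counts, accuracy / precision / recall /
  specificity / FPR / F1 with loud `NaN` flags on zero denominators, and
  trapezoidal ROC/AUC equal to the pairwise Mann–Whitney probability.
* **I/O and CLI**: NIfTI and NRRD volume round-trips, CSV manifests, a full
  `pipeline_run()` with a hashed provenance log, and a `nodulecam`
  command-line tool (`generate`, `audit`, `train`, `evaluate`, `explain`,
  `run`).

## Worked example

```r
library(nodulecam)

# 1. audit the lightweight 3D model against its published layer table
a <- audit(build_model(canonical_description("proposed3d"), seed = 1))
print(a)
#> Parameter audit for 'proposed3d'
#>    layer      kind realized printed corrected status
#> 1      1    conv3d     3472    3472        NA  match
#> 2      2 batchnorm       64      64        NA  match
#> 3      3    conv3d     2064    2064        NA  match
#> ...           (20 rows, every layer "match")
#> 17    17     dense    16640   16640        NA  match
#> 20    20     dense      514     514        NA  match
#> PASS: no mismatched layer counts

# 2. phantoms, split, train
ds  <- generate_dataset(phantom_config_easy(), 200, 200, seed = 1001)
sp  <- make_splits(ds$labels, train_fraction = 0.7, validation_fraction = 0.1,
                   seed = 1002)
mod <- build_model(canonical_description("proposed3d"), seed = 1003)
fit <- train(mod, ds, sp,
             train_config(epochs = 20, batch_size = 8,
                          early_stop_patience = NULL, seed = 1004))

# 3. score the held-out test split (once!)
rep <- evaluate_test(fit$model, ds, sp)
print(rep)
#> <metrics_report>
#>   accuracy     0.9667
#>   precision    1.0000
#>   recall       0.9333
#>   specificity  1.0000
#>   fpr          0.0000
#>   f1           0.9655
#>   auc          0.9672
#> <confusion_counts> tp=56 fp=0 fn=4 tn=60 (threshold 0.5)

# 4. explain one true positive
i  <- which(sp$split == "test" & ds$labels == 1)[1]
hm <- grad_cam(fit$model, ds$samples[[i]]$volume, class_index = 1)
png::writePNG(overlay(ds$samples[[i]]$volume, hm, slice_axis = 3),
              "overlay.png")
```

Accuracy, AUC and the confusion counts describe the held-out test split of
the phantom set; the heatmap marks the voxels that drove the nodule call.
(Numbers come from the run shown; other seeds vary within a few test
samples.) The phantom task is deliberately easy — the point of the
experiment is that architecture, training, explanation and evaluation are
verifiably correct, not that phantoms are hard.

## Command line

```sh
nodulecam audit --all                       # per-layer table, exit 3 on mismatch
nodulecam generate --out data --n-positive 100 --n-negative 100 --seed 7
nodulecam train --arch proposed3d --manifest data/manifest.csv --out run
nodulecam evaluate --checkpoint run/checkpoint.rds --manifest data/manifest.csv --split test --out run
nodulecam explain --checkpoint run/checkpoint.rds --input data/volumes/sample_0001.nii.gz --out run/cam
nodulecam run --out full_run --seed 7       # generate → train → evaluate → explain
```

Exit codes: 0 success, 1 usage error, 2 data error, 3 audit mismatch.

## What this package is not

The published headline results on the LUNA16 CT corpus (97.17% accuracy,
AUC 0.97) require the external 888-scan dataset and large-scale training;
nothing here reproduces them, and phantom metrics must not be read as
clinical performance. See the methods vignette
(`vignettes/nodulecam-methods.Rmd`) for the models, the numerical choices,
and the limits of what phantom-based validation shows.
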