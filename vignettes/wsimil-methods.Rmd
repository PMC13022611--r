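---
title: "Weakly supervised section classification: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised section classification: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Digitized tissue-section scans from endoscopic biopsies are far too large to
feed to a convolutional network whole, and pathologist labels exist only at
the section level: a section is normal or abnormal, and an abnormal section
may carry the phenotypes *active inflammation* and/or *chronic
changes/architectural distortion* (not mutually exclusive). `wsimil`
implements the resulting weakly supervised pipeline end to end:

1. **Tiling** — overlapping square patches with zero padding cover the whole
   scan; each patch is bilinearly downsized for the classifier.
2. **Patch QC** — an artifact/background CNN, then an Otsu tissue-fraction
   rule, remove uninformative tiles.
3. **Weak-label training** — every retained patch inherits its section's
   label (multiple-instance learning: the section is the labeled bag, its
   patches the unlabeled instances); one binary CNN is trained per task.
4. **Aggregation** — a section is called positive when more than 50% of its
   retained patches have predicted probability above 0.5.
5. **Evaluation** — patient-level 5-fold cross-validation with a full binary
   metric suite, plus Cohen's kappa for interobserver agreement and
   Grad-CAM heatmaps for interpretation.

## Tiling geometry

`grid_spec()` defaults to 4096-px patches with 25% overlap, i.e. stride
`round(4096 × 0.75) = 3072`, downsized to 128 × 128 by bilinear
interpolation. Origins start at 0 and advance by one stride per step; along
each axis the patch count is 1 when the extent fits one patch and
`ceil((extent − patch_size) / stride) + 1` otherwise, so the final tile may
run past the scan edge and is zero-padded. Coordinates are 0-based with
half-open extents, and the grid is emitted in row-major order. Under this
convention a 28,416 × 28,928 scan — a realistic median for whole-section
scans at 40× — yields 9 × 10 = 90 patches.

Two geometry choices were genuinely open and are fixed here as package
conventions: the origin lattice is anchored at 0 (trailing tiles absorb the
remainder as padding), and scans smaller than one patch yield exactly one
fully padded tile, so no section is ever discarded for being small.
Padding is applied before resizing; the pad mask is carried through the
resize and re-binarized at 0.5 so QC can distinguish true dark tissue from
zero fill.

## Patch quality control

QC order is fixed: the CNN filter first, Otsu second. The rationale is that
histogram thresholding alone cannot flag pen-mark or air-bubble artifacts —
pen strokes are dark and read as "tissue" to any luminance rule — while a
small texture classifier separates them easily.

* The artifact filter is a reduced-width instance of the patch classifier
  (filters 8/16/32/64). Its training set is *scan-derived*: the synthetic
  module renders small artifact-bearing scans, tiles them exactly as the
  pipeline does, and labels each patch from the ground-truth masks —
  reject for patches dominated by pen/bubble artifacts or bare slide,
  usable for patches with real tissue (normal or abnormal texture,
  including fragment edges); ambiguous patches between the class
  definitions are excluded. Training on pipeline-identical patches keeps
  the filter's decision boundary aligned with what it will see at
  inference (an earlier purely tile-rendered training set systematically
  rejected partial-tissue edge patches). A patch is rejected when its
  artifact probability exceeds 0.5 (strict).
* The tissue rule computes one Otsu threshold per scan on the
  padding-excluded luminance image, then drops retained patches whose
  fraction of sub-threshold (dark) pixels is **strictly below 0.20**.
  Computing Otsu per scan rather than per patch avoids the degenerate
  behavior of the criterion on homogeneous tiles. Tissue fractions are
  measured at the resized patch resolution.

The two stages partition every scan's patches into
`retained / artifact_rejected / low_tissue_rejected`; scans whose patches
are all rejected stay in the cohort as zero-instance bags and surface as
"no-call" sections in evaluation rather than being forced negative.

## The patch classifier

`cnn_config()` encodes the reference architecture: four convolutional sets
(3 × 3 kernels, ELU activation, batch normalization *after* the activation,
2 × 2 max pooling with stride 2, per-set dropout 0.1/0.15/0.2/0.25),
filters 16/32/64/128, L1 penalty 1e-4 on convolution kernels, then global
max pooling, a 256-unit dense layer with dropout 0.3, and a single sigmoid
output. Training uses Adam (learning rate 1e-4), binary cross-entropy,
batch size 4, at most 300 epochs with early stopping at patience 50, and
the checkpoint with the best validation accuracy is kept. Inputs are scaled
to [0, 1] by division by 255; no stain normalization or augmentation is
applied anywhere.

The forward/backward passes are implemented in this package (im2col + GEMM
convolutions in C++, the rest vectorized R) and verified against
finite-difference gradients in the test suite. Points where the reference
schedule is silent, decided here once:

* **Convolution padding** is "same" and pooling windows are 2 × 2, so four
  halvings take 128 to 8 — the only combination under which the deepest
  feature map is 8 × 8.
* The dense head's activation is ELU, matching the convolutional sets.
* **Validation accuracy for checkpointing is patch-level** (under weak
  labels), since model selection happens inside the training loop before
  any aggregation.
* Class imbalance is left untouched (no weighting or oversampling); the
  synthetic generator's class balance is the experiment's knob instead.
* Batch-norm running statistics use momentum 0.9; inference uses them and
  disables dropout, so prediction is deterministic.

Grad-CAM operates on the pre-sigmoid logit: channel weights are spatial
means of the logit gradient at a chosen conv set's pooled output (the
deepest by default), the weighted activation sum is rectified,
max-normalized, and bilinearly upsampled. An all-zero map is legal when
every gradient-weighted activation is non-positive.

## Aggregation

`aggregate_section()` applies the strict two-threshold rule: patch positive
iff P > 0.5, section positive iff the positive fraction exceeds 0.5. Both
inequalities are strict, so ties go negative — the literal reading of
"more than 50%". The 50% bag threshold (rather than the textbook "any
positive instance" rule) compensates the known bias of weak labels: most
patches of an abnormal section contain no abnormal tissue, yet all carry
label 1 during training.

Because the rule is binary, a continuous score is needed for ROC analysis;
the package defaults to the **positive fraction** itself (so the call is
exactly a threshold on the score) and offers mean patch probability as an
alternative. Only retained patches ever vote.

## Evaluation

`make_cv_splits()` shuffles patients under a seed and partitions them into
5 test groups; each fold draws 3 validation patients from the remainder.
All scans of a patient stay in one cohort — the split is the leakage
control, and the permuted-label null cohort (`permute_manifest_labels()`)
is the corresponding negative control: cross-validating against permuted
labels must give chance-level MCC.

Fold metrics: accuracy, balanced accuracy, precision, sensitivity,
specificity, F1, MCC, and AUC by the rank (Mann–Whitney) statistic with
midrank ties — robust for the coarse positive-fraction score. Across-fold
summaries use the **population** SD of the five fold values. Degenerate
folds (one-class test truth) report `NA` for the affected metrics and are
excluded from means with a defined-fold count, never zeroed. Phenotype
models are evaluated on *all* test sections; normal sections and
abnormal-but-other-phenotype sections count as negatives.

Cohen's kappa uses the marginal-product expected agreement and the
large-sample variance `po(1−po)/(n(1−pe)^2)` for its CI; the degenerate
`pe = 1` case is defined as 1 under perfect agreement and `NA` otherwise.

## The synthetic cohort generator

No public dataset accompanies this problem (single-institution patient
data), so `synth_params()` / `generate_cohort()` render seeded, fully
deterministic H&E-like scans with ground truth:

* near-white background (gray ≈ 247) with Gaussian pixel noise (SD 3);
* 3 elliptical tissue fragments per scan in pink-purple tones with gentle
  low-frequency luminance texture and pale crypt-like spots;
* in abnormal scans, one contiguous **witness region** covering 60% of the
  tissue area carries the abnormal texture: dense dark spots for active
  inflammation, oriented dark ridges for chronic changes, a mid-frequency
  mottle when neither phenotype applies, both overlaid when both apply —
  distinct signals so the phenotype models must learn different features;
* saturated pen strokes and bright bubble rings cover ~1% of the area.

Default rates mirror a realistic study regime: 25 patients, 41.2% abnormal
sections, phenotype prevalences 87.3% and 79.5% among abnormal sections,
granuloma recorded at 7.8% of abnormal sections but never modeled (too
rare to learn). The witness fraction of 0.6 makes the >50% aggregation
rule satisfiable on truly abnormal scans while leaving instance labels
genuinely noisy — both properties are asserted in tests.

What the generator does *not* emulate: stain variability, real crypt
architecture, scanner focus artifacts, or any photorealism. Passing tests
on synthetic cohorts therefore demonstrate that the pipeline's mechanics —
geometry, QC, weak-label learning, aggregation, split hygiene — are
correct and that the models can extract a localized texture signal; they
say nothing about accuracy on real histopathology.

## Desk-scale profile and problem sizes

The slide-scale defaults (4096-px patches, 128-px inputs, 300-epoch
schedule) are impractical for routine verification, so
`pipeline_config()` defaults to a size-parametric desk profile chosen once:
1024–2048-px scans, 128-px tiles (stride 96) resized to 32, a narrow
classifier (filters 8/16/32/64, dense 64), learning rate 1e-3, batch size
8, up to 4 epochs, and per-fold balanced caps of 600 training / 160
validation patches. The geometry is scale-free — the same code paths and conventions
run at either scale — and every threshold (0.5/0.5 aggregation, 20%
tissue, patient-level splits) is identical in both profiles.

## Numerical choices and degenerate inputs

* Otsu: first maximizer of between-class variance wins ties; constant
  images return the constant (tissue fraction 0 downstream).
* Bilinear resizing uses half-pixel centers with edge clamping; constants
  are preserved exactly and outputs never leave the input range.
* Fully padded patches have tissue fraction 0 by definition and are
  rejected.
* Empty probability vectors refuse to aggregate (no-call instead).
* Max-pool ties take the first (top-left) argmax; global-max-pool gradient
  flows to the first maximizer.
* All RNG flows from explicit seeds through small derived streams (scan,
  fold, stage), so cohorts are bit-identical and training is reproducible
  run-to-run on one platform.

## Known limitations

* The synthetic textures are deliberately easy; real-data performance
  claims are out of scope.
* The artifact filter is trained on synthetic labels, not on curated real
  patches; its threshold (0.5) is a convention, not a calibration.
* Granuloma is carried through manifests but unmodeled.
* Tissue fractions are measured on the resized patch, not at native
  resolution; the test suite bounds the resulting disagreement with the
  ground-truth mask oracle (≥95% agreement required).
* Training uses a single CPU code path; there is no GPU support.
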