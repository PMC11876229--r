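---
title: "Jigsaw self-supervised pretraining for mammography classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jigsaw self-supervised pretraining for mammography classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`jigsawmam` reimplements, end to end, a self-supervised pretraining study
for breast-cancer classification on mammograms: a jigsaw-puzzle pretext
task learns tissue structure without labels, the learned encoder is
fine-tuned to classify cancer vs not-cancer, and the result is evaluated
with the study's full protocol (patient-grouped repeated cross-validation,
Youden operating points, subgroup metrics, paired AUC tests, Grad-CAM).
Because the study's data (the Chinese Mammography Database, CMMD) and its
GPU-scale training are out of reach for a test suite, the package ships a
seeded synthetic phantom generator that emulates the statistical structure
of that population, and every stage runs at desk scale on one CPU.

This vignette records the methods and, importantly, the design decisions:
where the published description was ambiguous, what we chose, and why.

## The pretext task

A 512×512 crop is tiled into a 3×3 grid of 170×170 cells (512 = 3·170 + 2;
the two leftover pixel rows/columns are discarded). Within each cell an
independent 150×150 window is drawn with a uniform jitter of 0–20 pixels
per axis — the jitter realizes the *random gaps* between patches that
prevent the network from solving puzzles by edge continuity. The nine
patches are then reordered by a permutation drawn from a fixed 31-class
set, and the network must classify *which* permutation was applied.

```{r}
library(jigsawmam)
grid <- grid_spec()                       # 512 / 3x3 / 170 / 150 / 0..20
permset <- generate_permutation_set(n_extra = 30, pool_size = 2000, seed = 1)
img <- generate_record(synthetic_config(n_patients = 2), 1)$image
puzzle <- sample_puzzle(img, perm_label = 5, permset, grid, seed = 1)
```

Two conventions are fixed package-wide and pinned by tests:

* **Permutation semantics.** A permutation `p` means "grid slot `i`
  (row-major) receives the patch originally at position `p[i]`". The
  inverse convention would work equally well, but mixing the two is the
  classic source of silent bugs; the apply-then-invert round-trip test
  asserts the convention everywhere.
* **Per-patch standardization.** Each patch is independently standardized
  to zero mean and unit variance (constant patches become zero). The
  original description is silent on this; we standardize so the puzzle
  cannot be solved from absolute brightness gradients alone.

## The permutation set

The label space is the identity plus 30 permutations "having the greatest
Hamming distance from the correct permutation". All derangements of nine
items sit at the maximal distance 9, and there are 133,496 of them, so
maximal distance-to-identity alone does not determine the set, and the
published tie-break is unknown. We therefore use the construction of the
original jigsaw-pretraining formulation: sample a seeded pool of distinct
derangements (2000 candidates by default) and greedily add the candidate
whose *minimum* Hamming distance to the already-selected set is largest,
breaking ties by the larger mean distance, then by sampling order.

The study reports a mean Hamming distance of 8.086 for its 31
permutations. Averaged over the identity and 30 derangements, the mean
distance *to the identity* would be 270/31 ≈ 8.71, so 8.086 can only be
the mean over all 465 unordered *pairs* — we record this as an inference,
not a published fact. Our greedy construction lands near 8.17 on average
across seeds, inside the acceptance band of ±0.15 around 8.086 (purely
random derangement selection gives ≈ 7.9–8.0; the dispersion step is what
moves the statistic up into the reported range).

## Architectures

The pretext model is a context-free network (CFN): one *shared* encoder
is applied to each patch independently, per-patch features pass through a
shared linear projection with ReLU (the original CFN has such a layer;
the study does not say, so its width is configurable), and the projected
features are concatenated in fixed slot order into a final fully
connected layer with 31 logits. The downstream model is a single-stream
binary classifier with the *same* encoder specification, so pretext
weights transfer without shape mismatch; its head produces one logit and
the score is its logistic transform.

The study's encoder is a ResNet50 at GPU scale. Reproducing its numbers
is explicitly out of scope here; the encoder is pluggable behind
`encoder_spec()`, and the buildable default is a compact 4-block CNN
(3×3 convolutions, stride 2, ReLU, global average pooling) implemented in
RcppArmadillo with im2col/GEMM kernels. No deep-learning framework is
available in this environment, so forward and backward passes are
hand-written; they are verified against a naive R convolution and against
central finite differences (gradient errors ~1e-10), which we consider
the load-bearing tests of the package.

## Training and the four arms

Optimization mirrors the study exactly: Adam, learning rate 0.001, weight
decay 0, cross-entropy; batch 128 and 100 epochs for the pretext task,
batch 64 and 100 epochs for fine-tuning (both scalable down). Each pretext
step draws a training image, a uniform permutation label and fresh jitter.

The study compares four pipelines: `IN-Jig` (externally pre-initialized
encoder + jigsaw + fine-tune), `Scratch-Jig` (random + jigsaw +
fine-tune), `IN` (externally pre-initialized + fine-tune), `Scratch`
(fine-tune only). ImageNet pretraining itself is out of scope: the
"externally pre-initialized" arms accept any compatible checkpoint file,
and `pretrain_rotation()` produces a stand-in from a brief
rotation-prediction pretext so the four-arm comparison structure is
testable without downloads.

```{r}
data <- generate_dataset(synthetic_config(n_patients = 400, image_size = 96))
splits <- grouped_kfold(unique(data$manifest$patient_id), k = 5, trials = 10)
arm <- pipeline_arm("Scratch-Jig")
scores <- run_arm(arm, data, permset,
                  train_config("jigsaw", epochs = 20, batch_size = 16),
                  train_config("finetune", epochs = 20, batch_size = 16),
                  splits, grid_spec(96, 3, 32, 24, 8), encoder_spec())
```

Two protocol decisions deserve emphasis:

* **Pretraining is fold-local.** The study states that data were
  "separated by patient, ensuring a consistent process from pre-training
  to the downstream task"; whether pretext training used all images or
  only training folds is not stated. We take the strict reading:
  pretraining sees only each fold's training patients, and an intersection
  between training and validation patient sets aborts the run (enforced,
  not advisory).
* **Degenerate equivalence.** Within each (trial, fold), one encoder
  initialization is drawn and shared by the pretext and fine-tuning
  stages, so `Scratch-Jig` with zero pretext epochs is *identical* to
  `Scratch` — a tested contract that pins the arm plumbing.

## Evaluation

`roc_auc()` computes the Mann–Whitney AUC from ranks (ties count half)
with ROC points at every distinct threshold; `youden_cutoff()` scans the
distinct observed scores plus +Inf (predict positive at score ≥ cutoff,
ties broken toward the smallest cutoff). Subgroup metrics follow the
study: per-finding AUC over that finding's images, the normal
true-negative rate (fraction of normal images below the cutoff) where AUC
is undefined, and per-density AUC. Mean ROC curves are vertically averaged
on a fixed 101-point FPR grid. `grouped_kfold()` deals patients round-robin
after a trial-seeded shuffle (5 folds × 10 trials by default), and
`compare_auc_ttest()` performs the between-arm test on per-trial AUCs.
The study says only "t test"; we default to the *paired* test because arms
share trial and fold seeds, with the unpaired Welch test behind a flag.
95% intervals are mean ± 1.96·SE over trials.

`grad_cam()` explains the classifier: channel weights are spatially
averaged gradients of the positive logit with respect to the last
convolutional block's post-activation maps (the standard layer choice;
the study does not name one), and the rectified weighted sum is bilinearly
upsampled and min–max normalized.

## The synthetic generator

The generator's defaults *are* the study conditions, not tuned test
conveniences: the finding mixture (mass 1140 : calcification 570 :
distortion 60 : normal 1054 of 2824), per-finding cancer rates, the
dense-breast fraction (2377/2824), and lesion-mask area ranges centered on
the reported mean area fractions (mass 20.7%, calcification 25.2%,
distortion 57.5% of the crop) all come from the study's population tables,
which are shipped verbatim in `cmmd_reference_counts()` and
`cmmd_exclusion_counts()`.

Cancer must be *learnable but not trivial*: malignant masses get
spiculated boundaries and radiating rays, malignant calcification
clusters are tight and bright, malignant distortions swirl harder — the
qualitative radiological signs, rendered geometrically. Patients
contribute 1–2 images and share a density class, so grouped splitting has
real structure to respect. Full-field phantoms add a pectoral-muscle
wedge to exercise breast segmentation and the "normal crops from the
bottom 80% of the breast area" rule.

Limits worth stating: these are phantoms, not mammograms. The renderers
make no claim about CMMD's intensity statistics or lesion morphology
beyond the tabulated mixture/area anchors; distributional shapes
(uniform area draws, Gaussian texture) are our choices. The study's
headline AUCs (0.925/0.921/0.918/0.909) are *not* reproduction targets —
they need the real data and ~100-epoch ResNet50 training. What the
package asserts instead is the protocol (exact arithmetic, oracle-checked
metrics) and the direction of the headline effect: at desk scale
(~600 synthetic images, 96-pixel crops, 20+20 epochs, 5 seeds), the
median validation AUC of `Scratch-Jig` is at least that of `Scratch`.

## Desk-scale problem sizes

All test-time sizes are our own scaling choices, structured to preserve
the study's geometry: 96-pixel crops with a 3×3 grid of 32-pixel cells,
24-pixel patches and 0–8 jitter mirror 512/170/150/0–20; batch 16
replaces 128/64; 20–60 epochs replace 100. One deviation from the stated
file format: 16-bit grayscale images are written as TIFF rather than PNG,
because no installed writer emits 16-bit PNG; masks remain 8-bit PNG.

## Reproducibility

Every stochastic step is seeded through `withr` (no global RNG pollution):
identical configs reproduce bit-identical datasets, permutation sets,
training trajectories and heatmaps. `scripts/acceptance.R` recomputes the
permutation-set statistic from scratch:

```{sh}
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
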