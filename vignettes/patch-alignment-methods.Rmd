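---
title: "Patch-level image-text alignment: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-level image-text alignment: models, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patchalign)
```

`patchalign` trains a contrastive vision–language model whose patch tokens
act as local "Finding"/"No Finding" classifiers, and evaluates the
resulting patch probability maps with a distance-based, Hungarian-matched
FROC. This vignette is the package's account of the method: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where the
design was genuinely open and we had to commit.

## Model

One code path serves two scales, configured by `model_config()`:

* the **tiny preset** (`tiny_model_config()`): 64-px inputs, 8-px patches
  (an 8×8 grid of N = 64 tokens), encoder width 64, two transformer layers
  with two heads, shared-space width 32. It trains end-to-end on one CPU
  and is the scale at which all shipped experiments run.
* the **full-scale presets** (`fullscale_model_config()`): the patch-grid
  geometry of the standard CLIP backbones at 224-px input — grids of 7
  (ViT-B/32), 14 (ViT-B/16) and 16 (ViT-L/14) — with a 900-px bicubic
  intermediate and stride-2 convolutions in the downscaler, and the
  combiner at input 1024/hidden 2048. These presets fix geometry and are
  unit-tested for it; training them is outside desk scale.

Components, in data-flow order:

**Downscaler.** Raw images are resampled to the intermediate side with a
fixed separable Keys bicubic kernel (a = −0.5, half-pixel centres, edge
replication), passed through learnable 3×3 convolution blocks (+ReLU),
and landed on exactly `image_side` pixels by fixed bilinear interpolation
so the positional-embedding table is always valid. Gradients flow through
the convolution stage only; the resampling operators are parameter-free
linear maps. At tiny scale the intermediate side equals the encoder side
and a single stride-1 block is used, initialised to the identity kernel so
optimisation starts from a faithful resampling; at full-scale geometry
two stride-2 blocks descend from 900 px. The number, stride and
initialisation of blocks are configuration, not architecture.

**Encoders.** The image encoder is a pre-norm transformer over flattened
patch vectors plus a learnable class token and positional table; it
returns the class-token output **g**, the patch tokens **p** in row-major
grid order, and the positional rows **pE** aligned to **p**. The text
encoder is a two-layer transformer over a word-level tokenizer of the
fixture vocabulary; prompts here are bare class names, so a pretrained
language model would add nothing the objective can use — all the method
requires is a learnable text embedding.

**Projections.** The original projection *P* (encoder width → shared
width, no bias) is one weight matrix shared between the global embedding,
the text embedding, and the patch embeddings entering the combination
loss; the secondary projection *S* is an independent map of the same shape
feeding only the patch losses. Keeping the two paths separate is a typed
invariant of the implementation, and mixing them is treated as a bug by
the tests. All projected vectors are L2-normalized; an all-zero vector
normalizes to zero and yields similarity 0 by convention (with zero
gradient), which keeps early training defined if a head collapses.

**Heads.** *F* is a single bias-free FC layer across the patch axis
(weights w₁…w_N): the combined embedding is Σₙ wₙ p′ₙ, re-normalized. *M*
is the attention-pooling combiner: tokens are the elementwise sum of
selected patch and positional embeddings, a learnable class token is
prepended, a 2-layer/4-head transformer runs, and the L2-normalized class
token is the pooled embedding. Positional information therefore rides in
the tokens themselves, which is why the pooled output is invariant under
joint row permutation — a property the acceptance suite asserts.

**Temperature.** One learnable log-temperature, initialised to
log(1/0.07) and clamped to [1, 100] after exponentiation, scales every
similarity in all four losses. A single temperature is the coherent choice
for a single joint space.

## Losses

With `Label` the identity pairing of a batch of B ≥ 2 image–text pairs:

* `L_global = CE(scale · g′ t′ᵀ, Label)`, symmetrized over the
  image→text and text→image directions and averaged.
* `L_lcl` applies the identical contrastive loss to the F-combined,
  re-normalized patch embeddings.
* `L_patch`: per patch n, two-class logits
  `scale · [p″ₙ·bt0″, p″ₙ·bt1″]` with cross-entropy target Gₙ. Written as
  a single selected cosine similarity per patch, a cross-entropy needs
  both class scores; the two-logit softmax with target Gₙ is the unique
  reading that makes "CE over all patch logits" well-defined, and we apply
  the same resolution to the pooled logit below. The per-patch reduction
  is a **mean** by default so the loss magnitude is invariant to grid
  size; `patch_loss_reduce = "sum"` restores the literal summation.
* `L_c_patch`: the G = 1 patches (or one uniformly random patch on
  no-finding images) are pooled by M, S-projected, and classified against
  the prompt pair with target 1 on finding images and 0 on no-finding
  images. Supervising the random patch towards "No Finding" (rather than
  skipping the term) keeps the term defined on every image and is
  consistent with the patch loss at Gₙ = 0.

Totals are weighted sums (γ₁, γ₂ pretraining; λ₁…λ₄ finetuning), all 1 by
default — equal weighting is the study condition, and the weights are
exposed for ablation.

## Supervision masks and geometry conventions

Pixel coordinates are 0-based and half-open throughout; patches are
indexed 1-based (row, col). A patch is positive in the ground-truth mask
**G** when the union of the finding's boxes covers **strictly more than
10%** of the patch area. Coverage is exact rectangle-intersection area
with union handled by an x-sweep over per-patch clipped rectangles, so the
mask matches a 1-pixel rasterization oracle exactly on integer boxes.
Boxes are mapped from raw-image to encoder coordinates by the same uniform
scaling as the image resize before mask generation. Masks serialize to
run-length-encoded JSON for offline precomputation.

## Training

`fit()` runs SGD with momentum over per-batch autodiff tapes.

* **Learning-rate groups.** The FC heads and the combining transformer
  (P, S, F, M, and the temperature) train at 1e-2; the image encoder, text
  encoder and downscaler at 1e-4. At full scale the backbone is a
  pretrained model and P belongs to it; at tiny scale nothing is
  pretrained and P is a freshly initialised FC layer, so it is grouped
  with the heads — the split's purpose (protect slow-moving
  representation, let new linear maps adapt quickly) is preserved.
* **Momentum 0.9** (the standard choice for SGD in vision) and **batch size 8** at desk scale: with only a few hundred
  training images, smaller batches buy proportionally more SGD steps per
  epoch, which matters more than batch-level negative diversity at this
  scale.
* **Initialisation.** Encoders N(0, 0.02); heads Xavier-uniform with no
  bias terms (`init_new_layers()`, re-runnable and seed-reproducible);
  downscaler identity.
* **Sampling.** Finetuning draws training images with replacement with
  inverse-class-frequency weights normalised to sum to the dataset size,
  giving an expected within-batch positive rate of one half under heavy
  imbalance. Pretraining shuffles without weighting. No augmentations.
* **Normalisation.** Per-image min-max to [0, 1] followed by
  standardisation with the training split's mean/SD (recorded on the
  model and applied identically at inference). The min-max step emulates
  per-exam dynamic windowing of radiographs; note that on a pure-noise
  image it stretches the noise to full range, which makes the
  no-finding class harder than a fixed intensity scale would — a
  deliberate property of the benchmark, not an artefact.
* **Model selection.** A seeded 80/20 validation split is scored after
  every epoch with the zero-shot global classification AUC; the returned
  checkpoint is the argmax epoch. Training aborts with a diagnostic
  naming the first non-finite loss component.
* **Determinism.** All randomness (splits, sampling, random-patch
  selection) flows from the config seed through R's RNG; two runs with
  identical inputs are bit-identical, and checkpoints round-trip
  bit-identically through `save_checkpoint()`/`load_checkpoint()`.

## Inference and evaluation

`patch_prediction_map()` S-projects the patch tokens, correlates them with
the S-space embeddings of "No Finding" and the queried class, and softmaxes
the two scaled similarities per patch; the global score does the same with
g′ in P-space. `operating_threshold()` picks the largest threshold whose
validation TPR reaches the target (90% by default). The attention-map
baseline (`attention_map()`) takes the last encoder layer's class-token
attention, head-averaged, reshaped to the grid and min-max normalised — the simplest
faithful saliency extraction for this architecture; note that at tiny
scale it cannot condition on the text query. Both map types flow through the *identical* evaluator — the
FROC code has no map-type switch at all, which is the fairness requirement
of the comparison protocol.

The evaluator treats the probability grid as a low-resolution image:

* **Blobs** are connected components of supra-threshold patches
  (strictly `> t`), 4-connectivity by default with an 8-connectivity flag;
  a detection's centre is the patch centroid and its score the maximum
  patch probability.
* **Matching** minimises total centre-to-centre Euclidean distance (patch
  units) by Hungarian assignment, with pairs beyond the allowed radius
  forbidden. The allowed radius is `max(min_radius, floor(scale · s/2))`
  with `s` the box's shorter side in patch units and `min_radius = 1`:
  the hit criterion only demands a 1-patch floor and a radius that scales
  with relative box size, so the half-shorter-side formula is our
  documented default — it guarantees matched predictions lie
  within the ground-truth region, and `scale` is an exposed knob.
* **FROC**: the threshold sweep is the exact sorted set of observed patch
  probabilities (cheap at desk scale, and exact), computed efficiently by
  evaluating each image only at its own unique values and merging the
  per-image step functions. Raw FROC points can dip when lowering the
  threshold merges two blobs into one; the reported curve is the monotone
  running-maximum envelope in both coordinates, so sensitivity and
  average FP are non-decreasing as the threshold falls and
  `sensitivity_at_fp()` (max sensitivity among points with avg FP under
  the level) is well-defined.
* **AUC** is the rank-based ROC area (ties half-credit), delegated to
  pROC with a fixed direction and cross-checked in the tests against a
  pairwise-comparison oracle.

Multiple annotator boxes per finding are out of scope: the evaluator takes
one ground-truth set per image, matching the one-annotation-per-finding
protocol. IoU/mAP-style detection metrics are deliberately not provided —
the hit criterion is distance-based because coarse region identification,
not boundary overlap, is the clinical question.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the method needs:
a "No Finding" majority (per-class prevalences plus a no-finding
remainder), planted elliptical lesions of controllable diameter and
contrast — both larger and smaller than one patch — class-specific texture
(solid offset for odd class indices, striped for even) so classes are
separable by a tiny encoder, Gaussian background noise, tight boxes that
exactly bound each lesion's pixel support, and paired reports that are
bare class names. Defaults: background base 0.35, noise SD 0.08, lesion
contrast +0.35, one lesion per positive image — a high-contrast phantom
in the spirit of a detectability benchmark, not a realistic radiograph.

What it does **not** emulate: anatomy and its confounds, report language
variation, annotator disagreement, resolution loss from clinical
downsampling, or label noise. Passing the recovery experiments therefore
shows that the losses, optimisation and evaluator are wired correctly and
that the method recovers planted signal under its own assumptions; it
does not certify performance on real radiographs.

## Shipped experiment sizes

The experiments the test-suite and the acceptance script run were sized
as the package's study conditions: 600 training / 200 test images with
one large-lesion class (20–36 px on 64-px images) at prevalence 0.4,
3 pretraining + 10 finetuning epochs, three seeds for the recovery
experiment; and for the patch-size failure mode, 400/120 images with a
large (20–36 px) and a sub-patch (3–6 px) class at prevalence 0.3 each,
shared pretraining and 8 finetuning epochs per class. The expected
qualitative outcome of the second experiment is that sensitivity at
0.5 avg FP for the sub-patch class falls below the large class: a finding
smaller than one patch cannot dominate any patch's area, its mask is a
single patch at best, and the coarse grid representation bounds what the
patch classifier can see — the same patch-resolution limitation the
method exhibits at full scale.

## Known limitations

* Findings smaller than the patch size are poorly localised by
  construction (see above); smaller patches or hybrid local-attention
  backbones are the natural remedies and are out of scope here.
* The text pathway is a toy: a word-level tokenizer over the fixture
  vocabulary. Free-text reports would need a real language model.
* The attention baseline is class-agnostic at tiny scale.
* The autodiff tape is built for this model family (dense matrices,
  fused attention/normalisation ops), not a general-purpose framework.
* Training cost grows linearly with images × epochs; the tape is
  single-threaded R with BLAS doing the heavy lifting, which is ample at
  desk scale and unsuitable for full-scale pretraining.
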