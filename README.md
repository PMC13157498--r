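# patchalign

Weakly supervised abnormality localization from image–text pairs, in R.

Contrastive vision–language models trained on paired images and short
clinical-style text learn strong global semantics but poor spatial
grounding: the class token knows *whether* a finding is present, not
*where*. `patchalign` implements a patch-level alignment method that turns
such a model into a coarse localizer using only bounding-box supervision on
a patch grid: the per-tile token outputs of a vision transformer are
projected into the joint image–text space and aligned with "Finding" /
"No Finding" text embeddings, so that at inference the patch grid itself
becomes a low-resolution probability map of the queried finding. It is
aimed at researchers studying weakly supervised localization pipelines
(chest-radiograph style) who want a small, fully inspectable,
CPU-trainable implementation with an exact, oracle-tested evaluator.

## The model and losses

A learnable downscaler (fixed bicubic resampling to an intermediate side,
then convolution blocks the gradient flows through) feeds a patch-token
image encoder producing a global embedding **g**, patch embeddings
**p**₁…**p**_N (row-major over the grid) and positional embeddings **pE**.
A text encoder produces prompt embeddings **t**. Two projections map into
the shared space: the original projection *P* (used for **g**, **t** and,
for the combination loss, the patches) and a trainable secondary
projection *S* for patch-level classification. All similarities are cosine
similarities of unit vectors scaled by one learnable temperature.

Four loss terms, equally weighted by default:

- **L_global** — the symmetric contrastive cross-entropy between projected
  global image embeddings and text embeddings over a batch (the standard
  CLIP objective).
- **L_lcl** (linear combination loss) — a single bias-free FC layer *F*
  combines the *P*-projected patch embeddings across the patch axis; the
  combined, re-normalized embedding enters the same contrastive loss, which
  pushes spatial information into the patch tokens during pretraining.
- **L_patch** — per patch, two-class logits `scale * [p″·bt0″, p″·bt1″]`
  against the S-space embeddings of "No Finding"/the class prompt, with
  cross-entropy targets from the binary patch ground-truth mask **G**
  (a patch is positive when boxes cover strictly more than 10% of its
  area).
- **L_c_patch** — the in-mask patches and their positional embeddings are
  attention-pooled by a small transformer *M* (2 layers, 4 heads; class
  token output, L2-normalized), S-projected, and classified against the
  same prompt pair (target 1 on finding images; a random patch with target
  0 on no-finding images).

Pretraining minimizes `γ₁ L_global + γ₂ L_lcl`; finetuning minimizes
`λ₁ L_global + λ₂ L_lcl + λ₃ L_patch + λ₄ L_c_patch` with SGD, a
two-group learning-rate split (backbone 1e-4; FC heads and combiner 1e-2),
Xavier-uniform bias-free head initialization, and inverse-frequency
weighted sampling against class imbalance. Everything trains through a
small reverse-mode autodiff tape built into the package — no external deep
learning framework is required.

Evaluation follows the free-response ROC protocol: the thresholded
probability grid is segmented into connected blobs, blob centroids are
matched one-to-one to ground-truth box centres by Hungarian assignment
under a distance hit criterion (allowed radius scaled with box size,
floored at one patch), and pooled TP/FN with per-image-averaged FP trace
the FROC curve; `sensitivity_at_fp()` reads off sensitivity at 0.25 or 0.5
average false positives per image.

## Worked example

```r
library(patchalign)

# geometry: a ViT-L/14-style encoder at 224 px has a 16 x 16 patch grid
grid_shape(224, 14)
#> [1] 16

# boxes -> patch ground-truth mask (strict 10% area coverage)
g <- grid_spec(64, 8)
pg <- bbox_to_patch_mask(data.frame(x_min = 25, y_min = 5,
                                    x_max = 45, y_max = 27), g)
sum(pg$mask)          # patches supervised towards "Finding"
#> [1] 12
allowed_radius(data.frame(x_min = 25, y_min = 5, x_max = 45, y_max = 27), g)
#> [1] 1

# end-to-end at desk scale: simulate -> pretrain -> finetune -> evaluate
res <- run_demo(seed = 1)
#> simulating 600 train / 200 test images (seed 1)
#> pretraining (3 epochs)
#> finetuning on 'opacity' (10 epochs)
#> evaluating on the test set
#> test AUC 1.000 | sens@0.25FP 0.964 | sens@0.5FP 1.000
```

The demo generates 600 training and 200 test phantoms (one bright
elliptical lesion class at prevalence 0.4 on a noisy background), trains
the tiny preset (64-px images, 8-px patches, width-64 two-layer encoders)
and evaluates zero-shot patch prediction maps. The three numbers are the
global zero-shot classification AUC on the test set and the FROC
sensitivities at 0.25 and 0.5 average false positives per image — high
sensitivity at sub-1 FP rates is exactly the regime a clinically useful
localizer must occupy. Fitted objects are tidyverse-friendly:
`tidy(fit)` returns the per-epoch history, `glance(froc)` the summary
sensitivities, and `autoplot()` draws FROC curves, prediction maps and
training histories.

A thin command-line wrapper with `simulate`, `train`, `infer`, `evaluate`
and `demo` subcommands is installed at
`system.file("cli", "patchalign", package = "patchalign")`.

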