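---
title: "Methods: ensemble attention/residual U-Nets for benign-malignant prostate segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble attention/residual U-Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Problem and scope

`glandseg` implements binary semantic segmentation of prostate tissue:
every pixel of an H&E image patch is classified as benign (0) or
malignant (1), where the malignant class is the union of Gleason
pattern 3 (discrete well-formed glands) and Gleason pattern 4 (fused
glands) — the early, hardest-to-spot patterns of acinar
adenocarcinoma.  The package covers the full workflow: annotation
rasterization and patch preprocessing, three U-Net-family
architectures trained with a composite Dice + focal objective,
Jaccard/Dice/mean-IoU evaluation, softmax ensembling with
grid-searched model weights, paired t-test comparison of methods, and
slide-level probability-map reconstruction.

Because clinical slide collections cannot be redistributed, the
package ships a seeded synthetic generator producing gland-like toy
patches and slides with pixel-accurate ground truth; the entire
pipeline is exercised end-to-end on those.

## Annotation model and preprocessing

Annotations use an 11-label taxonomy (`annotation_labels()`):
background (`Bg`), unspecific foreground (`Fg`), normal glands (`N`),
`GP3`, `GP4`, `GP5`, lymphoid (`L`), not-evaluated (`NE`), not-sure
(`NS`), `PIN`, and `Blood`.  Polygons rasterize by a pixel-centre
even-odd rule, later polygons overwriting earlier ones so nested
regions are listed outer-first.  Binarization maps GP3 and GP4 to 1
and everything else to 0; GP5 is excluded from the malignant class by
design (the binary task targets *early* patterns), as are NE/NS/PIN.

Patches are cut on a regular grid (default 256 px, stride = patch
size, 0-based `(row, col)` indices, half-open pixel ranges — the fixed
convention that makes slide reconstruction exact).  Two quality
predicates drop a patch: tissue fraction below 20%, and absence of any
annotated-tissue label (patches that are purely background,
foreground, or a mixture of the two).  "Tissue" is defined
operationally as a pixel whose minimum RGB channel is at or below
220/255 — a standard whiteness mask; since the source description of
the 20% "pixel ratio" is not operational, the threshold and the basis
of the ratio (image whiteness vs. annotated mask) are both exposed as
arguments, with image whiteness as default.

Class weights for training are inverse-frequency balanced at the pixel
level, `w_c = N_total / (2 N_c)` over the training masks.  Published
weights of 0.68 / 1.85 for this task are consistent with this scheme
(their ratio equals the benign:malignant pixel ratio); whether the
original counts were pixel- or patch-based is not stated, so the basis
is a function argument.

## Architectures

All three families share one encoder-decoder skeleton
(`model_spec()`): `depth` levels with channel counts doubling from
`base_filters`, 2×2 max pooling on the way down, nearest-neighbour
upsampling + 3×3 convolution on the way up, skip connections level by
level, and a 1×1 convolution head producing two channels normalized by
a per-pixel softmax (kept two-channel rather than a single sigmoid to
match the H×W×2 one-hot output contract exactly).

* **U-Net** — forward convolutional units (two 3×3 conv + ReLU, batch
  norm optional but on by default) and plain skip concatenation.
* **AU-Net** — the same units, with each skip passed through an
  attention gate before concatenation.
* **ARU-Net** — residual units (conv path plus identity or 1×1
  projection shortcut, ReLU after the addition) and attention gates.

The attention gate average-pools the skip to the gating signal's
resolution, maps both into an inner space of `skip_channels / 2`
channels by 1×1 convolutions, adds, applies ReLU, reduces to one
channel (ψ), squashes through a sigmoid, nearest-upsamples the
coefficient map, and multiplies the skip by it.  Coefficients are
therefore bounded in [0, 1] and a zero skip always yields zero output.

Defaults are depth 5 and base 16 at 256 px input (the reference
configuration); tests and the desk-scale pipeline use depth 3 / base 8
at 64 px, which preserves every architectural element at ~1% of the
compute.  Parameter counts order as ARU-Net > AU-Net > U-Net at equal
spec, since gates and projections only add parameters.

No deep-learning framework is involved: forward and backward passes
are implemented in the package (compiled im2col+GEMM convolutions,
pooling, batch norm; the rest in vectorized R), with analytic
gradients verified against central finite differences in the test
suite.  This makes runs exactly reproducible from a seed — weight
initialization (He-normal), shuffling, and the optimizer are all
deterministic, with no hidden nondeterministic kernels.

## Training objective

The loss is `Dice_loss + focal_multiplier * BinaryFocal_loss`
(`loss_config()`, multiplier 1 by default).

The Dice term is built from *soft* precision and recall per class:
soft TP = Σ y·p, FP = Σ (1−y)·p, FN = Σ y·(1−p), each ratio guarded by
a `smooth` constant (default 1e-5) in numerator and denominator so
perfect hard predictions score exactly 1.  Per class,
F<sub>β</sub> = (1+β²)·P·R / (β²·P + R), and the loss is the
class-weight-normalized sum of (1 − F<sub>β</sub>).  Weights are
normalized to sum 1, so only their ratio matters.

The focal term, on the malignant channel with natural logarithm and
probabilities clipped to [1e-7, 1−1e-7], is the mean of
`−y·α(1−p)^γ·log p − (1−y)·α·p^γ·log(1−p)`.  Note α multiplies *both*
terms in this formulation, so γ = 0, α = 1 reduces it exactly to
binary cross-entropy (a property the tests pin against an independent
implementation).

β, α, γ are named but not valued in the source description; defaults
β = 1 (symmetric Dice), α = 0.25, γ = 2 follow the established focal
conventions the formulation matches, and all are configurable.  The
Dice term aggregates globally over the batch (per-image averaging is
the natural alternative; global was chosen as it matches how soft
counts are usually accumulated and is the stabler estimator for small
batches).

## Training regime

Adam with initial learning rate 1e-4, up to 100 epochs by default,
monitoring validation Jaccard: the rate is multiplied by 0.5 after 5
epochs without improvement (floored at 1e-6; these schedule constants
are package choices, the source states only the mechanism), and the
returned model is the best-validation-Jaccard checkpoint.  Masks are
delivered as complementary two-channel one-hot arrays matching the
softmax head.  Batch size defaults to 16; the desk-scale acceptance
regime uses 8, scaling the batch down with the ~100× smaller dataset
so that an epoch still delivers a reasonable number of updates.  No
augmentation is applied by default.

## Ensembling and comparison

The model ensemble (ME) averages the per-pixel softmax vectors of the
three trained models; the weighted ensemble (WME) uses a weighted mean
with weights found by exhaustive grid search over the lattice
{0, 0.2, …, 1}³ (step configurable), scored by overall mean IoU on the
validation split, ties resolved to the lexicographically smallest
tuple.  Weights are normalized by their sum — the reference weight
tuple (0.0, 0.2, 0.4) does not sum to one and its source never states
whether normalization occurs; normalizing keeps the output a valid
probability field and cannot change the argmax.  Hard labels are the
per-pixel argmax with exact ties going to benign.

Methods are compared by a two-tailed paired t-test
(t = mean(d)/(sd(d)/√n), sample sd, df = n−1).  What constitutes one
paired observation is not specified at the source (its t values are
consistent with n = 3); the pipeline pairs per-repeat overall mean IoU
over k seeded validation subsamples (default k = 3, 70% subsampling),
which is stated here as a package convention, not a reconstruction.

## Slide-level score maps

Patch predictions are written back into their grid cells to form a
slide-sized malignant-probability mosaic.  Cells whose patches were
quality-filtered are *missing* (`NA`), not probability zero — filtered
patches are a documented source of apparent false negatives, and
conflating "not predicted" with "benign" would hide that; a zero-fill
mode exists for fidelity with renderings that do conflate them.
Overlap (if a sub-patch stride is ever used) averages the covering
predictions.  Overlays alpha-blend a dark-green→red ramp over the
slide RGB, missing cells showing the original tissue.

## The synthetic world

`generate_patch_pair()` draws stylized H&E-like patches: pink stroma
with sparse nuclear speckle, whitish lumina, purple epithelium.
Morphology follows the grading descriptions at toy scale — benign:
few large rings with wide lumina; GP3-like: many small, non-touching
rings; GP4-like: fused blobs built as unions of overlapping ellipses.
A `crowding` parameter (0.2 / 0.6 / 0.85 by default) controls nuclear
density: it raises speckle density and darkens the epithelial tone,
emulating the hyperchromatic, crowded nuclei of malignant glands.
That appearance gradient is what makes the toy task learnable by small
networks in minutes; it is a deliberate simplification.  Channel noise
is additive Gaussian, σ = 8/255.  Default gland coverage is 25% for
benign and GP3-like patches and 40% for GP4-like ones, giving training
sets with roughly a quarter malignant pixels — the same imbalance
regime the published class weights imply.  Toy slides are white
canvases with elliptical tissue cores carrying labeled sub-regions;
the label raster is produced by rasterizing the very polygons the
generator emits, so the polygon→raster round trip is exact by
construction.

What the generator does *not* emulate: stain variability, scanner
artifacts, pyramidal multi-resolution formats, tissue folds, the
morphological ambiguity between well-differentiated carcinoma and
benign glands (in real tissue GP3 can look deceptively normal and may
require immunohistochemistry to call), and annotation noise.  A green
test on synthetic data therefore establishes that the pipeline's
mechanics — shapes, gradients, filtering, reconstruction, ensembling —
are correct and that the architectures can learn a structured
segmentation task; it says nothing about clinical performance.

## Numerical choices

* Probability clipping at 1e-7 in the focal term; `smooth = 1e-5` in
  soft precision/recall and metrics (1.0 optional for metric
  conventions that use it).
* Two Dice forms: the *literal* printed formula divides by the union
  and exceeds 1 for overlapping masks (it equals 2·Jaccard up to
  smoothing); the *conventional* form divides by the mass sum and is
  the reporting default, since published scores bounded by 1 imply it.
  The discrepancy is surfaced, not guessed away.
* Mean IoU over one-vs-rest confusion counts; a class absent from both
  truth and prediction scores 1 by default (configurable).
* Max-pooling ties take the first element in scan order, so gradients
  never double-route; argmax ties go to class 0.  Both tie-breaks are
  deterministic and documented.
* Batch-norm: momentum 0.9, ε = 1e-5, population variance in batch
  statistics; inference uses running moments.
* He-normal initialization, seeded; Adam β₁ = 0.9, β₂ = 0.999,
  ε = 1e-8.

## Known limitations

* Training is CPU-bound R/C++; it is sized for desk-scale experiments
  (minutes at 64 px, depth 3), not for 10⁵-patch clinical corpora.
* Exact bit-reproducibility assumes the same BLAS and thread count
  between runs (single-threaded BLAS is the tested configuration).
* The synthetic appearance gap above means hyperparameters tuned here
  do not transfer to real H&E data.
* `NE`/`NS` pixels map to benign in the binary target; an
  ignore-in-loss mode is a natural extension but is not implemented —
  on real data those regions are better excluded than asserted benign.
* Single-resolution rasters only; no pyramidal WSI I/O.
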