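---
title: "ihcseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ihcseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative breast-cancer immunohistochemistry (IHC) scores — the fraction
of tumor nuclei positive for ER, PR or Ki-67, or the membrane staining
pattern for HER2 — are defined over *invasive carcinoma* (IC) regions only.
Ductal carcinoma in situ (DCIS), normal ducts and lobules, and immune
infiltrates must be excluded from the count. On an IHC whole-slide image
(WSI) the interiors of DCIS and IC nests look nearly identical; what
separates them is boundary morphology: DCIS grows inside ducts and keeps a
continuous (myoepithelial) rim and a large rounded outline, while IC forms
small, irregular, infiltrating nests. `ihcseg` implements a two-stage
training framework for segmenting background / DCIS / IC in IHC images, a
context-aware tiled WSI inference scheme, and the downstream mask-conditioned
Ki-67 index that the segmentation enables — all testable end-to-end on a
procedural synthetic-data generator with exact ground truth.

## The segmentation network

The model is a three-branch fully convolutional network with output stride 8:

* a **detail (P) branch** of medium depth that keeps a stride-8 feature map;
* a **context (I) branch**, deepest, running at stride 16 with a
  global-average-pooled context unit (a bottleneck MLP added back to the
  feature map) for long-range aggregation, projected and bilinearly
  upsampled back to stride 8;
* a **boundary (D) branch**, shallow, emitting one-channel boundary logits
  `plB`.

The sigmoid of `plB` acts as spatial attention in the final fusion:
`F = a * P + (1 - a) * I`, so the detail branch dominates exactly where the
boundary head fires. Three heads are emitted: the auxiliary class scores
`plS` (on P), the main class scores `pl` (on the fused features), and `plB`.
Because the boundary gate feeds the fusion, the boundary head receives
gradient both from its own loss and through the main head — the attention is
live wiring, and a test asserts that clamping it changes `pl`.

There is no deep-learning runtime in this R stack, so the network — forward,
backward, and SGD with momentum — is implemented from scratch in
RcppArmadillo (im2col + GEMM convolutions). Backprop is verified against
central finite differences to ~1e-7 relative error. Normalisation is
per-sample instance normalisation with affine parameters rather than batch
normalisation: it is deterministic at evaluation, has no running statistics
to serialise, and behaves identically at any input size, which the
fully-convolutional contract (256-px training crops, 2048-px multi-scale
crops) requires. The `tiny` preset (~105k parameters) trains on one CPU;
`S`/`M`/`L` scale the widths.

## Losses

With `gs` the class mask, `gB` the boundary band, and per-pixel probabilities
from the upsampled heads:

* `l0`, `l2`: weighted cross-entropy of `plS` and `pl` against `gs`;
* `l1`: weighted binary cross-entropy of `plB` against `gB`;
* `l3` (boundary-aware CE): cross-entropy of `pl` restricted to pixels where
  the boundary probability exceeds a threshold `t` (default 0.8), normalised
  by the total pixel count. With that normalisation the loss is monotonically
  non-increasing in `t` (the indicator set only shrinks), which is asserted
  as a property test. No gradient flows through the indicator.

The supervised objective is `Ls = λ0·l0 + λ1·l1 + λ2·l2 + λ3·l3` with
defaults λ = (0.4, 20, 1, 1), the convention of the three-branch
architecture family (the source protocol leaves the values empirical). All
reductions are means over pixels, so `Ls` is invariant to batch size and
resolution.

Two deviations from the written contract are worth recording. First, the
boundary band definition: the band contains pixels within Chebyshev distance
`width_px - 1` of a 4-neighborhood class transition, because that is the
reading consistent with the worked example (an 8×8 half/half split at width
1 gives exactly the two transition columns); the default width 2 gives a
4-pixel band. Second, the default class weights are
`(1/frequency)^0.5` rather than plain inverse frequency: on nest-sparse
tiles the raw 10:1 weighting made background errors so cheap that the model
painted tumor everywhere (measurably worse held-out mIoU);
`class_weights_from(power = 1)` restores the plain version.

The training loop evaluates losses and their gradients through a fused C++
path for speed; the R implementations remain the public API and a test
asserts the two routes agree to 1e-9 on random maps.

## Stage 1: semi-supervised consistency training

Unlabeled images contribute through weak/strong consistency. Each unlabeled
image yields three views sharing one geometric transform (scale in
[0.5, 1.5], crop, flips) — sharing is necessary because the loss compares
maps pixelwise — and differing photometrically: the weak view `xw` is
geometry-only, the strong views `xs1`, `xs2` add independent color jitter
(occasionally grayscale mix or blur; no CutMix, since color jitter is the
named strong example). Four probability maps enter the objective: `pw`
(weak, gradient-detached), `ps1`, `ps2` (strong), and `pfp` from the
feature-perturbation flow — the weak view's fused features with
expectation-preserving channel dropout (rate 0.5) before the main head.
The consistency loss gates every pixel by pseudo-label confidence
`max pw ≥ τ` (τ = 0.95) and weighs the feature stream by λ_fp = 0.5 and the
two image streams by μ/2 = 0.25, with H realised as hard-pseudo-label
cross-entropy. It is computed on the stride-8 maps the heads emit (the
contract does not fix a resolution; stride 8 avoids three more gigapixel
upsamplings per step). `pw` and `pfp` share one backbone forward, so an
unlabeled item costs three forwards, not four.

Optimisation is SGD (lr 0.001, momentum 0.9, weight decay 5e-4) with
polynomial decay (power 0.9). Desk-scale defaults are 256-px crops, 20
epochs, batch 1 (more updates per tile at the stated learning rate); the
`paper` profile keeps 1024-px crops and 300 epochs. Every random draw —
shuffle order, augmentation, dropout masks — is derived from
`(seed, stream label, epoch, step)` via a hash, which gives two guarantees
that are tested bitwise: resuming from a checkpoint (parameters + momentum
buffers) reproduces the uninterrupted trajectory, and a labeled-only run
equals an `unlabeled_weight = 0` run.

## Stage 2: multi-scale fusion, and WSI inference

Tile-by-tile inference loses cross-tile context. The multi-scale model takes
a context window of side S (4096 in the published geometry; 512 at desk
scale), and predicts the central S/2 crop three ways through the *frozen*
backbone: the four S/2 corner crops reassembled into a stride-8 mosaic and
center-cropped (`p1`), the center crop directly (`p2`), and the whole window
downscaled to S/2, center-cropped and bilinearly upsampled 2× (`p3` — the
downscale branch covers 4× the area, so its matching central window is half
the output side; the 2× upsampling is our resolution fix, the source leaves
it unstated). Two attentional feature fusion (AFF) modules blend them in
order `AFF(AFF(p1, p2), p3)` — detail first, context last. Each AFF computes
a channel-attention gate `g = sigmoid(local 1×1 bottleneck MLP +
global pooled bottleneck MLP)` over `a + b` and returns the convex blend
`g·a + (1-g)·b`; with zero-initialised final biases the initial gate is 0.5.
Stage-2 training fits only the AFF parameters with cross-entropy against the
center ground truth nearest-downsampled to the output side; the backbone
hash is asserted identical before and after.

WSI inference tiles the image with S/2 cores on a stride-S/2 grid (an exact
partition, half-open rectangles, 0-based row-major coordinates), builds each
core's S-context with reflect padding at borders, runs the branch triplet
and the AFF cascade, and writes the argmax into the core of a stride-8 label
mask; cores without tissue (HSV saturation below 0.05 after 5×5 median
smoothing on an overview) are skipped. The stride-8 mask is the stored
artifact (a gigapixel level-0 mask is pointless memory-wise); export paths
upsample nearest or emit QuPath-compatible GeoJSON polygons.

## Ki-67 quantification

RGB tiles are unmixed by Ruifrok–Johnston color deconvolution with the
standard H-DAB vectors (`OD = -log10((I+1)/256)` projected on the stain
basis). The synthetic generator composes images through exactly this forward
model, so round trips are exact by construction and are tested below
quantisation noise. Nuclei are detected on the smoothed total nuclear OD
(hematoxylin + DAB, Gaussian σ 1.0, threshold 0.22), split by a
marker-based watershed whose markers are intensity-dome peaks found per
stain channel — a faint hematoxylin nucleus pressed against a bright DAB
nucleus has no peak in the total map or the distance transform, but a clear
dome in its own channel — flooded on the total smoothed OD, filtered by area
(5–400 px²), and called positive when mean DAB OD exceeds 0.2 (a stand-in
for the external tool the source delegates to). These detector settings were
fixed by measuring recall and index error against the generator's nucleus
ledger. The Ki-67 index is
`100 · n+ / (n+ + n-)` over detections whose *centroid* falls in the scored
region — everything (`no_mask`), tumor classes {1,2} (`tumor_mask`), or IC
only (`ic_mask`); centroid assignment keeps the index independent of
detection order and tile decomposition. Agreement against reference scores
reports Pearson r and the mean and SD of `estimate - reference` in
percentage points (negative mean = underestimation).

The cohort experiment in the acceptance suite rebuilds the qualitative
phenomenon that motivates masking: with lymphocyte aggregates (always
marker-negative) and DCIS whose positivity exceeds IC's, unmasked scoring
underestimates grossly, the tumor mask over-counts DCIS, and the IC mask is
both accurate (within ±3 points of ledger truth per case) and the most
stable (smallest error SD). The reference score of a synthetic case is its
ledger IC index — the analogue of a pathologist scoring the invasive region.

## The synthetic world

The generator emulates the structure the method's assumptions rest on, not
histology photorealism:

* **DCIS**: 1–3 large rounded nests (radius 32–56 px at 256 px), low-harmonic
  outlines, a continuous 2-px darker rim;
* **IC**: several small nests (radius 9–20 px) with high-harmonic jagged
  outlines — so the class cue lives in boundary morphology, as in tissue;
* **confounders**, always background-labeled: normal lobules (acinar rings of
  nuclei) and dense lymphocyte aggregates (small, dark, marker-negative);
* **stains**: nuclear DAB for ER/PR/Ki-67 positives, membrane (ring) DAB for
  HER2, hematoxylin counterstain everywhere, composited in optical-density
  space and quantised to 8 bits;
* **ground truth**: class masks, derived boundary bands, per-nest placement
  logs, and a nucleus ledger (position, class, marker positivity) from which
  true Ki-67 indices are computed exactly.

Everything is bit-reproducible from the spec + seed (placement is
rejection-sampled with deterministic scene retries). What a green test does
*not* establish: robustness to scanner variation, stain variation beyond the
jitter model, crush/fold artifacts, nuclear pleomorphism, or any claim about
the published numbers on real WSIs — those were measured on a private
dataset and are explicitly out of scope here.

## Numerical and design choices

* Bilinear resampling is top-left aligned (`src = dst · in/out`), so
  upsampling by f leaves source samples exact at multiples of f; the loss
  path upsamples stride-8 logits ×8 and backpropagates through the exact
  adjoint.
* Probabilities are clipped at 1e-12 inside logs; losses are means over
  pixels.
* Stage-1 evaluation mIoU is computed at stride 8 against the
  nearest-downsampled mask (the resolution the model predicts at).
* Checkpoints are a flat numeric state vector (+ momentum buffers when
  resumable) plus a JSON sidecar with architecture, seed, epoch and a
  content hash — no pickled objects.
* The desk-scale acceptance run (tiny preset, 200 tiles, 20 epochs, lr
  0.001) reaches held-out mIoU ≈ 0.61 deterministically; the semi-supervised
  and context-benefit direction checks run at reduced sizes to stay inside
  the CPU budget, asserting direction (≥ 0 improvement, 3-seed median), not
  magnitude.
* Pseudo-WSIs are stored as PNG rather than tiled TIFF (no TIFF codec in
  this R stack; pixel content identical, lossless).

## Limitations

The network is a compact interpretation of the three-branch design, not a
line-by-line replica of the cited architecture; depth/width presets above
`tiny` are provided but untested at scale. Training at the published scale
(1024-px crops, 300 epochs, 4096-px context) is configured (`paper` profile)
but far outside CPU budgets. Nucleus detection is classical morphology, not
learned, and inherits its usual failure modes on overlapping nuclei.
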