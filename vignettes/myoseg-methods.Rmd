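---
title: "myoseg: models, post-processing, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{myoseg: models, post-processing, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myotubes — the multinucleated cells formed when skeletal-muscle myoblasts
fuse — are quantified in culture by three morphological features: tube
diameter, tube length, and the number of nuclei per tube. Manual measurement
of these features from two-channel fluorescence images (a myosin-heavy-chain
stain for the tubes, DAPI for the nuclei) is slow and notoriously
inconsistent between researchers, because myotubes branch, overlap, and have
no canonical shape, and because nuclei cluster and overlap.

`myoseg` implements an automated pipeline for this measurement task:

1. a **multi-task convolutional network** that jointly predicts three
   per-pixel probability maps — myotube mask, nuclei mask, and nuclei
   *centroid* map — from the two-channel image;
2. a **marker-controlled watershed** that separates overlapping nuclei using
   the predicted centroids as seeds;
3. **medial-axis skeletonization** of the myotube mask with branch
   decomposition, from which diameters and lengths are measured;
4. evaluation utilities (IoU/Dice, image-level 5-fold cross-validation, six
   classical auto-threshold baselines);
5. a **synthetic scene generator** with exact ground truth, so that every
   stage of the pipeline is testable without microscope data.

## The network

The segmentation model is a residual encoder–decoder with three class
heads. For a `(2, 512, 512)` input:

| stage            | operation                                     | output            |
|------------------|-----------------------------------------------|-------------------|
| down 1           | 3×3 conv, stride 2; instance norm; ReLU       | 64 × 256 × 256    |
| down 2           | 3×3 conv, stride 2; instance norm; ReLU       | 128 × 128 × 128   |
| residual × 5     | (3×3 conv, batch norm, ReLU, 3×3 conv, batch norm) + identity | 256 × 128 × 128 |
| up 1             | 3×3 transposed conv, stride 2; instance norm; LeakyReLU | 128 × 256 × 256 |
| up 2             | 3×3 transposed conv, stride 2; instance norm; LeakyReLU | 64 × 512 × 512 |
| head × 3         | 5×5 conv, stride 1; sigmoid                   | 1 × 512 × 512     |

The reference design lists the residual stack at 256 channels while the
second downsampling block outputs 128. We honor both figures by inserting a
1×1 channel-doubling projection before the residual stack and a 1×1
reduction after it (the default); `model_config(strict_128 = TRUE)` instead
keeps 128 channels throughout. This was a genuinely open design point; the
projection variant is the default because it reproduces every stated
dimension.

The network is fully convolutional: any input whose spatial dimensions are
divisible by 4 (two stride-2 stages) produces maps of the input size.
`base_channels` scales the width of every stage together; 64 is the
full-size network, and smaller values give proportionally thinner networks
that train in minutes on one CPU — the test suite uses `base_channels = 8`
with the full depth (2 down, 5 residual, 2 up, 3 heads) unchanged.

Training minimizes the sum of per-head mean binary cross-entropies,

$$L_k = -\tfrac1N \sum_i \left[ y_i^k \log \hat y_i^k + (1 - y_i^k)
\log (1 - \hat y_i^k)\right], \qquad
L_{\text{total}} = \lambda_1 L_{\text{myotube}} + \lambda_2
L_{\text{nuclei}} + \lambda_3 L_{\text{centroid}},$$

with Adam (learning rate 0.001, $\beta_1 = 0.5$, $\beta_2 = 0.999$). The
loss weights $\lambda$ are not specified in the source design; the default
is $(1,1,1)$, configurable. Unstated numerical details were fixed as
follows and are recorded in the config: Kaiming-normal weight
initialization, prediction clamping to $[10^{-7}, 1-10^{-7}]$ inside the
loss, binarization of sigmoid outputs at 0.5, LeakyReLU slope 0.2,
non-affine instance norm. Batch statistics are the per-channel spatial
statistics (batch size 1), which keeps evaluation deterministic for fixed
weights. The implementation (forward, backward, Adam) is in
Rcpp/RcppArmadillo, since no deep-learning runtime is assumed; gradients
are verified against central finite differences in the test suite.

Centroid labels need one caveat: a single marked pixel per nucleus is a
degenerate BCE target (the empty prediction is almost optimal), so training
targets dilate each centroid dot by 2 px (`make_labels_from_truth`,
configurable). Downstream, centroid *predictions* are used only through
their connected components, so the dilation radius does not bias counts.

## Preprocessing

Channels are min-max normalized to $[0,1]$ **per image** (the source
states only "normalized to grayscale"; per-image normalization makes the
pipeline invariant to acquisition gain, and is configurable). A constant
channel maps to zero. Training images are tiled into non-overlapping
512×512 patches and augmented with the three 90° rotations — at full
scale, 40 images of 2048×2048 yield 40 × 16 × 4 = 2560 training patches.
Rotation is counter-clockwise by exact multiples of 90°, so no
interpolation touches the labels. Full-image inference uses tiling with a
configurable overlap (default 0) and per-pixel mean blending; at zero
overlap, tile-then-stitch is exactly the identity. Train/test splits and
cross-validation folds are made at the *image* level, never the patch
level, to avoid leakage.

## Marker-controlled watershed

Markers encode certainty: the complement of the nuclei mask dilated by 3 px
is the background marker; each connected component of the centroid map is a
nucleus marker; everything else (the nuclei bodies plus a 3 px band) is
unknown. Flooding assigns unknown pixels in non-decreasing relief order.
A pixel reached by one nucleus flood takes its label; a pixel reached by
two or more distinct nucleus floods becomes the watershed line, so lines
separate *objects* from each other. The background flood claims whatever
no nucleus reaches first and never forms a line — an isolated nucleus is
labelled without a line around it. Choices the source leaves open, fixed
here:

* **relief**: negated Euclidean distance transform of the nuclei mask
  (water rises from nucleus centres) — the standard marker-controlled
  choice;
* **connectivity**: 4 for flooding and instance adjacency, 8 for skeletons;
* **tie-breaking**: FIFO within a relief level with deterministic
  row-major seeding, so results are reproducible bit-for-bit;
* pixels walled off from every marker by the line are assigned to the line.

The implementation is a priority-queue flood; the tests require exact
agreement with a naive linear-scan reference on randomized overlapping-
nuclei scenes.

## Skeletons and morphometry

Myotube masks are thinned by iterative two-subiteration boundary peeling
(Zhang–Suen) until stable, which preserves topology and is idempotent.
Skeleton pixels with ≥ 3 neighbours are junctions, with exactly 1 are
endpoints; branches are the maximal junction-free paths (junction pixels
are shared by their branches; a closed ring is one cyclic branch).

Per-branch measurements:

* **diameter**: the local width at a skeleton pixel is `2*EDT` px, where
  EDT is the Euclidean distance to the nearest background pixel centre.
  For tubes rendered as continuous bands of geometric width $w$ — the
  generator's strokes, at any orientation — this recovers $w$ to within
  one pixel (the skeleton sits within half a pixel of the true axis and
  the nearest background centre within half a pixel of the boundary, and
  averaging along the branch cancels most of the quantization). On
  axis-aligned masks built from whole pixel rows it reads one pixel high,
  since background centres sit half a pixel beyond the ink on both sides;
  no constant offset can be exact for both discretizations, and the
  continuous-band convention is the one the ±1 px recovery contract is
  stated for. Samples within 2 px of a junction are excluded (the EDT
  inflates where branches meet); branches shorter than 5 px are flagged
  and excluded from per-myotube rollups.
* **length**: sum of per-step distances along the ordered path, 1 px for
  axis-aligned steps and $\sqrt 2$ for diagonal steps.
* **nuclei per myotube**: a watershed instance belongs to a myotube when
  its centroid pixel lies inside that myotube's mask.

All physical quantities scale by `um_per_px`. The magnification of the
source data is not stated anywhere alongside its micron tables, so the
generator records an explicit `um_per_px` (default 1.0) in its manifest
rather than guessing one.

## The synthetic world

The generator renders what the pipeline assumes about real scenes, with
exact ground truth:

* **myotubes**: constant-width strokes along random smooth splines
  (default widths 5–13 px at the 128×128 test scale), forking with
  probability 0.3 so skeleton branch extraction has nontrivial cases;
* **nuclei**: filled ellipses (semi-major 4–7 px), with a target fraction
  (default 0.2) placed overlapping a previous nucleus; overlapping regions
  are attributed to the nearest centre in the instance labels, and every
  instance contains exactly its own single-pixel centroid;
* **intensities**: background ≈ 0.1, foreground ~ U(0.6, 1); both are
  attenuated by a linear illumination ramp in a random direction with
  maximal relative depth `background_gradient` (default 0.75), then
  additive Gaussian noise (σ = 0.08, a peak-signal-to-noise of roughly 6 —
  ordinary for cell-culture fluorescence) and clipping to [0,1].

The illumination model deserves a note. The stated world requires global
auto-thresholds to fail on gradient scenes the way they fail on real
microscope images (bright regions force a threshold that erases dim tube
ends). A purely additive background offset cannot produce that regime while
foreground stays constant-bright, so the ramp is multiplicative
(vignetting) and applied to both classes: at depth 0.75 the dim-end
foreground (≈ 0.15) overlaps the bright-end background (≈ 0.1 + noise), so
no single threshold separates the classes, while local contrast (≈ 6×)
remains for the network. These defaults are fixed once as the package's
stated world and are not tuned per test.

What the generator does **not** emulate: point-spread-function blur,
realistic shot noise, out-of-focus debris, touching *myotubes* of similar
intensity, or 3D structure. A green synthetic test therefore establishes
that the pipeline's logic is correct under its stated assumptions — not
that any particular accuracy will transfer to real acquisitions.
Full-scale accuracy claims would require expert-annotated microscope data
and full-scale training, both out of desk scope.

Scenes serialize to plain-text formats only: ASCII PGM (16-bit for
channels, binary for masks, label-valued for instances) plus a CSV
manifest. This keeps datasets diff-able and dependency-free; no binary
image libraries are required anywhere in the package.

## Evaluation and baselines

IoU (`TP/(TP+FP+FN)`) and Dice (`2TP/(2TP+FP+FN)`) are computed from exact
pixel confusion counts; the identity `Dice = 2·IoU/(1+IoU)` is enforced in
tests to 1e-12. Empty-vs-empty mask pairs define both metrics as 1 (logged);
empty-vs-nonempty as 0 — the source is silent on the convention. Centroid-map
IoU, if compared, should dilate both prediction and truth by the training
radius, since point-set IoU is ill-conditioned.

The six auto-threshold baselines (IsoData, Li, Mean, Minimum, Otsu, Yen)
operate on 256-bin histograms of the normalized channel, following their
classical definitions: Otsu maximizes between-class variance; Yen maximizes
the entropic correlation criterion; IsoData iterates to the fixed point
`t = (μ_below + μ_above)/2`; Li iterates the minimum-cross-entropy map;
Mean thresholds at the image mean; Minimum smooths the histogram with a
3-point running mean until exactly two modes remain and splits at the
valley. Tests check Otsu and Yen against exhaustive objective sweeps and
the iterative methods against their fixed-point definitions.

## Reproducibility

Every stochastic stage takes an explicit seed: scene specs, weight
initialization, epoch shuffling, fold assignment. Identical spec + seed
reproduces scenes bit-for-bit; identically-seeded training runs produce
identical histories. Pipeline outputs embed a hash of the configuration,
and the ground-truth-mask pipeline mode is byte-reproducible.

## Known limitations

* The trainer is single-threaded CPU with batch size 1; it is meant for
  desk-scale experiments and tests, not for reproducing full-scale
  training runs.
* Zhang–Suen thinning can retain rare two-pixel-wide diagonal staircases;
  branch decomposition tolerates them, and idempotence is exact, but
  skeletal lengths can differ by a pixel or two from other thinning
  families.
* Watershed relief is the distance transform, not intensity; strongly
  non-convex overlapping nuclei may split along geometric rather than
  photometric boundaries.
* The statistical test in `summarize_groups` is a plain Welch t-test
  provided as a convenience; the source material does not name its test,
  and no multiple-comparison correction is applied.
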