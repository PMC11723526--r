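# myoseg

Automated morphometry of skeletal-muscle myotubes from two-channel
fluorescence microscopy.

## The problem

When myoblasts differentiate they fuse into myotubes — elongated,
branching, multinucleated cells. Drug studies on muscle (atrophy,
sarcopenia, dystrophies) quantify myotube cultures by **tube diameter**,
**tube length**, and **nuclei per tube**, measured from paired
myosin-heavy-chain (tube) and DAPI (nuclei) stains. Manual measurement is
slow and varies badly between researchers because myotubes overlap and
branch and nuclei cluster. `myoseg` automates the measurement:

* a **three-headed residual encoder–decoder** (2 stride-2 downsampling
  blocks → 5 residual blocks → 2 transposed-conv upsampling blocks → three
  5×5-conv sigmoid heads) jointly predicts per-pixel probability maps for
  the myotube mask, the nuclei mask, and the nuclei *centroids*, trained
  with the summed per-head binary cross-entropy
  `L = λ₁L_myotube + λ₂L_nuclei + λ₃L_centroid`
  under Adam (lr 0.001, β₁ = 0.5, β₂ = 0.999);
* a **marker-controlled watershed** floods the nuclei mask from the
  predicted centroids over a distance-transform relief, separating
  overlapping nuclei with explicit watershed lines
  (`W(p) = mᵢ` when all labelled neighbours agree, watershed line
  otherwise);
* **medial-axis thinning** reduces each myotube to a one-pixel skeleton,
  decomposed into branches at junction pixels; diameter is profiled along
  each branch as `2·EDT − 1` px and length as the sum of unit/√2 steps;
* **IoU / Dice** evaluation with image-level 5-fold cross-validation and
  six classical auto-threshold baselines (IsoData, Li, Mean, Minimum,
  Otsu, Yen) for comparison;
* a **synthetic scene generator** (bright branching tubes + overlapping
  elliptical nuclei + illumination gradient + noise, with exact ground
  truth) so the full pipeline is testable offline.

Everything — including the network's forward/backward passes and Adam, the
watershed, the thinning and the distance transform — is implemented in
R/Rcpp with no deep-learning or image-library dependencies; images travel
as plain-text PGM.

## Worked example

Generate a small synthetic cohort, train the (width-reduced) network, and
quantify a control-vs-treated contrast where the treated group is rendered
with 30% thinner tubes:

```r
library(myoseg)

# 1. two groups of synthetic scenes: control tubes 10 px, treated 7 px
specs <- c(
  lapply(1:3, function(s) scene_spec(n_tubes = 1, tube_width_range = c(10L, 10L),
                                     tube_curvature = 0, branch_prob = 0, seed = s)),
  lapply(4:6, function(s) scene_spec(n_tubes = 1, tube_width_range = c(7L, 7L),
                                     tube_curvature = 0, branch_prob = 0, seed = s)))
man <- generate_dataset(specs, "scenes")

# 2. quantify from ground-truth masks (model-free validation mode)
cfg <- pipeline_config(man, groups = rep(c("control", "treated"), each = 3),
                       use_truth_masks = TRUE)
res <- run_pipeline(cfg)
summarize_groups(res$per_image, reference = "control")
```

```
    group n_images diameter_mean diameter_sd nuclei_mean nuclei_sd single_image
1 control        3      9.973221  0.09075322   0.6666667  1.154701        FALSE
2 treated        3      6.866751  0.05216703   0.0000000  0.000000        FALSE
  diameter_delta_pct nuclei_delta_pct  p_diameter  p_nuclei
1            0.00000                0          NA        NA
2          -31.14811             -100 9.10585e-06 0.4226497
```

The measured group means recover the rendered widths (10 and 7 px at
1 µm/px) to within the ±1 px contract of the diameter operator, and the
diameter delta against the control group reports the built-in −30%
effect (nuclei-per-myotube counts are near zero here because a single
thin tube covers little of the frame; nuclei are only counted when their
centroid falls inside a tube). The same pipeline runs from a trained
checkpoint by replacing `use_truth_masks = TRUE` with
`checkpoint = "model.rds"` (see `train_model()` / `save_checkpoint()`),
in which case the maps come from the network and are stitched from tiles
for large frames.

A width-reduced network (`base_channels = 8`, full depth) trained for 10
epochs on 50 synthetic 128×128 scenes reaches held-out myotube IoU 0.93
and nuclei IoU 0.88 in a few CPU-minutes, while the six auto-threshold
baselines score 0.60–0.81 on the same gradient-illuminated scenes with
an order of magnitude more spurious skeleton branches — the test suite
(`tests/testthat/test-acceptance.R`) reproduces this end to end.

There is also a thin CLI over the same functions:

```sh
exec/myoseg simulate --out scenes --n 6 --seed 1
exec/myoseg quantify --manifest scenes/manifest.csv \
    --groups control,control,control,treated,treated,treated \
    --use-truth-masks --out results
```

## Acceptance script

`scripts/acceptance.R` rebuilds the full-width network from its default
configuration, runs a forward pass on a `2 × 512 × 512` input, and writes
the measured architecture dimensions (channels after the first
downsampling block; spatial size of each class-head output map) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                  synthetic scenes, data I/O, model, post-processing,
                    metrics/baselines, pipeline
src/                Rcpp/Armadillo: network fwd/bwd + Adam, distance
                    transform, thinning, watershed, components
tests/testthat/     unit + property + acceptance suites (oracle-checked)
vignettes/          methods vignette: models, conventions, limitations
exec/myoseg         command-line wrapper
scripts/acceptance.R
```
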