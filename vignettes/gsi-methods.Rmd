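---
title: "Gait skeleton templates: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait skeleton templates: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsigait)
```

## The representation

A walking sequence observed by a depth sensor or a monocular pose
estimator is a series of 3D joint positions. `gsigait` collapses such a
sequence into a fixed-size grayscale image — a *gait skeleton template* —
in which pixel intensity is the fraction of frames in which that pixel was
covered by the rendered skeleton. Two variants exist: **lines** (bones
drawn as capsules of thickness *t*) emphasize body connectivity, and
**joints** (discs of radius *r*) emphasize individual joint trajectories.
The classical silhouette-based **GEI** (mean of aligned binary
silhouettes) is implemented as the baseline under the same canvas
geometry. All three feed the same compact CNN, so differences in
recognition behaviour are attributable to the input representation.

## The 17-keypoint body model

Source layouts differ (Kinect-v2: 25 joints; MediaPipe: 33 landmarks), so
both are mapped onto one 17-keypoint tree: the axial chain
head–neck–shoulder_center–spine_center–hip_center and four limb chains
through shoulders/elbows/wrists and hips/knees/ankles (16 edges, no
cross-limb links). Hands, feet and facial landmarks are discarded: distal
extremities carry the largest tracking error at gait-observation distances
while contributing little gait signal, and far-side joints are frequently
occluded in lateral views — they are dropped rather than reconstructed, so
rendering skips edges with an invalid endpoint instead of extrapolating.

Conversion rules live in YAML tables (`inst/extdata/*_to_gsi17.yaml`):
direct copies, midpoints, and discards. Two conventions are the package's
own, since the source layouts force a choice:

* **MediaPipe head/neck.** MediaPipe has no neck landmark; the package
  uses the nose as the head point (the most stable facial landmark at gait
  distance) and defines the neck as the midpoint of head and shoulder
  center. Midpoint confidence is the minimum of its inputs (conservative).
* **Kinect axis flip.** Kinect's z axis points away from the camera; the
  converter negates z so that all internal geometry uses one frame:
  x right, y up, z toward the camera.

## View normalization

Each sequence is aligned to a canonical lateral orientation by a single
homogeneous matrix

$$M_{view} = R_z(\theta_z)\, S\, R_y(\theta_y)\, T,$$

applied to every joint as $p' = M_{view}\,p$. The factors are estimated as
follows, and each estimator is a design choice worth recording:

* $T$ translates the **sequence-mean hip center** to the origin. The
  alternative anchors (first-frame or per-frame hip) are either sensitive
  to a single noisy frame or destroy the trajectory needed by the next
  step; per-frame anchoring is deferred to the later translation
  normalization.
* $\theta_y$ rotates the walking direction into the X axis. The direction
  is the total-least-squares line through the horizontal (XZ) hip-center
  trajectory, oriented first-to-last frame — a trajectory-based estimator
  is far more robust to per-joint pose noise than a torso-normal estimate.
  Hip displacement below 1 cm is a degenerate (stationary) trajectory and
  raises an error. The rotation is limited to ±90°; if the walk then heads
  toward −X, the reflection $S = \mathrm{diag}(-1,1,1,1)$ flips it, which
  makes left-to-right and right-to-left recordings of the same gait land
  on identical templates (mirror consistency).
* $\theta_z$ makes the mean torso axis (hip center → shoulder center)
  vertical, removing residual in-plane tilt. It is estimated once per
  sequence, not per frame, to avoid injecting frame-rate jitter into the
  render.

Because $M_{view}$ is rigid up to reflection, all intra-frame pairwise
distances are preserved (the suite checks this to 1e-9 over random rigid
transforms).

Translation normalization then subtracts each frame's hip X and Z from all
joints of that frame. Y is deliberately untouched: the vertical hip
oscillation is part of the gait signature and survives into the template.

## Projection and canvas fit

Orthographic projection drops Z. One global bounding box over all frames
of the sequence is scaled so its height is 90% of the 80×120 px canvas and
centered; the identical scale and offset apply to every frame, so limb
excursion across the cycle stays comparable between frames. The 90% margin
keeps thick strokes from clipping at the canvas border. Two consequences
are intentional and documented rather than assumed: absolute body size is
not preserved across subjects (each sequence fills 90% of the canvas), and
within-sequence proportions are preserved exactly (doubling all world
coordinates yields the identical projection). Pixel centers sit at integer
+ 0.5; the image origin is top-left with v growing downward.

## Cycle segmentation

The detection signal is the horizontal ankle separation |u_left −
u_right|, mean-subtracted and smoothed by a centered moving average of
ceiling(fps/10) frames (~0.1 s). The separation peaks at every step, i.e.
twice per stride, so boundaries are placed at every *second* local maximum
— same-foot strike to same-foot strike. This estimator was chosen because
it is computable from the 17-keypoint set alone and is standard in
template-based gait work. If fewer than two maxima exist (near-stationary
or heavily smoothed input) the whole sequence becomes one cycle, with a
warning: segmentation is total, every trial yields a template. A minimum
cycle length of four frames guards against noise-split boundaries. The
default template aggregates all frames spanned by the detected cycles; a
`per_cycle` option emits one template per cycle instead.

## Rendering and accumulation

Rasterization is binary with hard footprints and no anti-aliasing: a pixel
is set iff its center lies within t/2 of a bone segment (capsule) or
within r of a joint (disc). This makes the renderer exactly equal to a
brute-force per-pixel distance test — the suite asserts bit-equality
against an independent full-canvas oracle — and removes any dependence on
a graphics library's line-drawing conventions. Footprints are monotone in
t and r by construction.

Accumulation is the pixel-wise arithmetic mean across frames, mirroring
the energy-image family; a max-accumulation (union mask) is available
behind a config flag. Values stay in [0,1] and are fed to the CNN as-is,
without rescaling to full dynamic range. Rendering parameters were
evaluated over {2, 4, 6, 8, 10, 12} px (`sweep_params()`); 8 px is the
default for both variants — small values fragment under noise, large ones
blur fine kinematic detail.

Templates are stored as 8-bit grayscale PNG (`round(v·255)`), which is
lossless to within 1/255 — ample for CNN input — and universally viewable.
Sequences are stored as JSON-lines with one frame per line and a header
carrying layout/fps/metadata; coordinates are serialized at 17 significant
digits so files round-trip bit-exactly.

## The synthetic cohort

The simulator generates a planar-dominant kinematic chain: the hip center
advances at stride-length × cadence with a vertical bounce at twice the
stride frequency; hip and knee angles are sinusoids with antiphase legs,
arms swing antiphase to their ipsilateral legs, and limb segments have
fixed lengths, so bone lengths are exactly constant in the noise-free
limit. Per-subject parameters are drawn uniformly from realistic adult
ranges (thigh 0.38–0.48 m, shank 0.36–0.46 m, cadence 0.8–1.2 Hz, hip
swing 0.32–0.55 rad, …) keyed deterministically by (seed, subject-id), so
identity is a stable kinematic signature and trials of one subject differ
only in their noise realization. Measurement error is i.i.d. Gaussian on
every coordinate (default σ = 5 mm, the scale of good depth-sensor joint
tracking); the viewing angle is applied last as a rigid yaw.

Covariates are emulated qualitatively: a carried bag (BG) suppresses arm
swing on the carrying side to ≤30% of its amplitude; a coat (CL) biases
torso/hip keypoints outward by up to 3 cm and adds extra joint noise.
These perturbation models are calibrated only to reproduce the *ordering*
of difficulty (CL harder than BG) — no attempt is made to match published
benchmark accuracies, which depend on the real datasets.

What passing tests on this cohort do **not** show: robustness to real
pose-estimator failure modes (temporally correlated jitter, left/right
swaps, occlusion dropouts), to segmentation errors in silhouettes, or to
the appearance diversity of real clothing. The simulator's role is to give
every pipeline stage a ground truth — cadence, view, identity — that real
data cannot provide.

## Recognition harness

The network is a compact two-block CNN: conv 18@7×7 → batch-norm → ReLU →
2×2 max-pool, conv 45@5×5 → batch-norm → ReLU → 2×2 max-pool, fully
connected 1024 (the embedding) → dropout 0.5 → linear softmax. Filter
counts and the 1024-unit layer follow the established compact
gait-recognition architecture this design descends from; batch-norm and
dropout are the stabilizing additions. Conv biases are omitted because the
batch-norm shift absorbs them. The same configuration is reused verbatim
for lines, joints and GEI inputs, so comparisons isolate the
representation. Convolutions are lowered to BLAS matrix products via
im2col/col2im kernels written in C++ (with a fused batch-norm/ReLU); the
backward pass is verified against finite differences to ~1e-9 relative
error in the test suite.

Training: cross-entropy; AdamW (lr 1e-3, decoupled weight decay 1e-4 on
weight matrices only) with a cosine schedule and 5-epoch linear warm-up
for the leave-one-trial-out protocol, plain constant-rate Adam for the
gallery/probe protocol; batch size 32; early stopping with patience 10 on
validation loss, restoring the best parameters. The LOTO validation split
is the last training trial per subject; training is deterministic given
the seed (shuffling, initialization and dropout all derive from it), up to
BLAS summation order.

Two protocols:

* **LOTO** (closed set): trials 1–8 train (trial 8 validating), trials
  9–10 test; the metric is softmax accuracy on held-out trials of *seen*
  subjects.
* **Gallery/probe** (unseen identities): the softmax head cannot classify
  subjects absent from training, so probes are matched to gallery entries
  by cosine distance between 1024-d penultimate embeddings — the standard
  choice in this architecture family; ties break to the lowest gallery
  index for reproducibility. Rank-1 is tabulated per gallery-view ×
  probe-view × covariate cell, and `summarize_matrix()` /
  `covariate_report()` recompute all means from cells, rounding only at
  output.

The shipped published benchmark tables carry one known internal
inconsistency: the printed 90° column mean of the joint-template
cross-view table (30.01) does not equal the mean of its printed column
entries (31.44). The package keeps the printed row verbatim as data and
recomputes summaries from entries, so both readings are available; the
discrepancy is documented here rather than silently replicated.

## Problem sizes and numerical choices

The bundled checks use a 10-subject × 10-trial lateral cohort at 30 fps
and 4 s per trial — enough for 3–4 strides per trial and strong identity
separability, while keeping a full train/evaluate cycle in minutes on one
core. Training caps at 60 epochs for these runs (the cosine period);
early stopping typically ends training near epoch 25. Rigid-geometry
identities are asserted at 1e-9 (accumulated floating-point error across
a handful of 4×4 products), pipeline-level agreements at 1e-6, and the
noise-free cross-view template agreement at mean absolute difference
≤ 0.02, which absorbs single-pixel rounding differences at stroke borders
after a 36–90° yaw is undone.

## Known limitations

* Perspective effects are ignored: projection is orthographic, appropriate
  for subjects a few meters from the camera, not for close-range wide-angle
  footage.
* No temporal smoothing or gap-filling of joints is performed; noisy input
  translates directly into template blur.
* The gallery/probe matching rule (cosine on embeddings) is a documented
  convention — trained metric heads would likely do better.
* Absolute benchmark accuracies on real datasets are out of scope: they
  require the original recordings, and the synthetic cohort is not a
  substitute for them.
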