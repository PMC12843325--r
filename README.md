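# gsigait

Skeleton-based gait recognition with compact 2D motion templates.

Gait is a behavioural biometric: people can be identified from how they
walk. The dominant appearance-based descriptor, the **Gait Energy Image
(GEI)**, averages size-normalized binary silhouettes over a gait cycle and
is highly accurate when viewpoint and clothing are controlled, but degrades
sharply under cross-view, coat (CL) and bag (BG) covariates. **Gait
Skeleton Images (GSI)** are the skeletal analogue: per-frame renderings of
a 3D-tracked skeleton — either lines along the bones (GSI-Lines, thickness
`t`) or discs at the joints (GSI-Joints, radius `r`) — accumulated over
time into one grayscale template that a standard 2D CNN can classify.

`gsigait` implements the full pipeline:

1. **Topology unification** — Kinect-v2 (25 joints) and MediaPipe (33
   landmarks) sequences are converted to a common 17-keypoint body model
   (axial chain plus four limb chains; hands, feet and facial landmarks
   dropped; central-axis keypoints formed by midpoints where the source
   lacks them). Mapping tables ship as YAML in `inst/extdata/`.
2. **View normalization** — each sequence is rigidly aligned into a
   canonical lateral orientation in homogeneous coordinates,

   `M_view = Rz(θz) · S · Ry(θy) · T`,

   where `T` moves the mean hip center to the origin, `Ry(θy)` rotates the
   estimated walking direction onto the X axis, `S = diag(-1,1,1,1)` flips
   walks heading toward −X, and `Rz(θz)` removes residual torso tilt. Being
   rigid, the map `p' = M_view · p` preserves all inter-joint distances.
3. **Trajectory removal and projection** — per-frame horizontal (X, Z) hip
   translation is subtracted (vertical oscillation is kept), depth is
   dropped orthographically, and the sequence is scaled onto a fixed
   80 × 120 px canvas (body box at 90% of the canvas height).
4. **Cycle segmentation and rendering** — stride boundaries are detected at
   every second maximum of the smoothed ankle-separation signal; frames are
   rasterized as hard capsules/discs and averaged into the template.
5. **Recognition** — a compact two-block CNN (18×7×7 and 45×5×5 filters,
   each with batch-norm/ReLU/2×2 max-pool, a 1024-unit embedding layer,
   dropout 0.5, softmax), trained with AdamW (lr 1e-3, weight decay 1e-4,
   cosine schedule with 5-epoch warm-up, early stopping patience 10) for
   the leave-one-trial-out (LOTO) protocol, or Adam for the gallery/probe
   protocol where unseen identities are matched by cosine distance between
   embeddings. Rank-1 accuracy is reported per gallery-view × probe-view ×
   covariate cell.

A parametric walking simulator (`simulate_sequence()`, `make_cohort()`)
generates labelled 3D walking cohorts — per-subject limb lengths, cadence
and swing amplitudes, plus viewpoint and bag/coat covariate perturbations —
so every stage of the pipeline is testable without external datasets.

## Worked example

```r
library(gsigait)

# simulate a 10-subject x 10-trial lateral-view cohort, 5 mm joint noise
man <- make_cohort(n_subjects = 10, trials_per_subject = 10,
                   views = 90, covariates = "NM", seed = 1,
                   noise_sigma = 0.005)

# render joint-based templates at the default 8 px radius
man <- add_templates(man, gsi_config("joints", param = 8))
man$template[[1]]
#> <gait_template> joints, 80x120 px, 96 frame(s), support 38.2%

# leave-one-trial-out: train on trials 1-7 (trial 8 validates), test 9-10
res <- run_loto(man, train_config("loto", max_epochs = 60, seed = 1))
res$accuracy
#> [1] 100
```

The printed support is the fraction of canvas pixels the walking skeleton
ever covers; the LOTO accuracy is the percentage of the 20 held-out trial
templates whose softmax argmax recovers the right subject — on this
well-separated synthetic cohort the network identifies all of them. A
cross-view, cross-covariate report comes from the gallery/probe protocol:

```r
gal <- man[man$trial <= 4, ]
prb <- man[man$trial > 4, ]
rep <- evaluate_gallery_probe(gal, prb, res$model)
glance(rep)
#> # A tibble: 1 x 4
#>   covariate same_view_mean cross_view_mean grand_mean
#>   <chr>              <dbl>           <dbl>      <dbl>
#> 1 NM                   100             NaN        100
autoplot(rep)      # rank-1 heatmap per view pair
```

The published CASIA-B cross-view matrices for GSI-Joints and GEI, and the
covariate table, ship as CSVs and load with `published_benchmarks()`;
`summarize_matrix()` and `covariate_report()` reproduce their aggregate
rows (same-view means, grand means, degradation in percentage points).

A thin CLI wraps the same functions
(`inst/cli/gsi simulate|render|sweep|train|eval`).

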