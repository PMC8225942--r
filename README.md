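# icgflow

Quantitative blood-flow analysis for indocyanine green (ICG) video
angiography, as used to assess STA-MCA bypass surgery (superficial
temporal artery to middle cerebral artery anastomosis, the standard
revascularisation for moyamoya disease). During surgery the cortex is
filmed under near-infrared light while ICG washes in; vessels brighten as
the dye arrives, and the wash-in pattern encodes each vessel's flow
direction and the tissue's perfusion timing. `icgflow` turns such videos
into quantitative read-outs:

- **Synthetic generator** — branching vessel phantoms with logistic
  dark-to-bright wash-in, sensor noise, known arrival times, known flow
  direction, and pre/post acquisition pairs related by a known similarity
  transform. Every downstream stage is testable against this ground truth.
- **Segmentation** — a multi-task U-Net (one encoder, two decoders) that
  segments all vessels and the recipient vessel simultaneously, trained
  with the weighted joint negative log-likelihood
  `L = alpha * L_all + beta * L_receip`, four-fold flip augmentation and
  five-view test-time averaging; evaluated by Dice and Jaccard.
- **Registration** — SIFT keypoints (difference-of-Gaussian extrema,
  128-dimensional descriptors) on the segmented vessel maps, Lowe ratio
  test at 0.8, RANSAC transform estimation with intensity-based polish;
  success rule: vessel-pixel overlap >= 35% and >= 10 correspondences.
- **Optical flow** — pyramid Horn-Schunck flow (smoothness weight
  `lambda = 2`, 4 levels, energy-difference stopping threshold 0.1) and a
  per-vessel direction verdict: forward, reverse, middle-to-both-sides
  (the post-bypass pattern), or indeterminate, plus pre/post change
  detection.
- **Perfusion** — ROI time-luminance curves, delay time (time to first
  maximum brightness), and a per-pixel time-to-peak colour map from red
  (early) to blue-purple (late).
- **Statistics** — Cohen's kappa with interpretation bands, percent
  agreement, the paired t-test and a normal Q-Q check, for comparing two
  categorical readings of the same cases.

## Worked example

Generate a synthetic bypass case — forward flow before, middle-to-both-sides
after, with the microscope moved between acquisitions — and run the
analysis:

```r
library(icgflow)

tree <- generate_vessel_tree(seed = 2, shape = c(192, 192), n_branches = 5)
pair <- generate_pre_post_pair(
  tree,
  wash_in_spec(direction = "forward", duration = 8),
  wash_in_spec(direction = "middle_to_both_sides", duration = 8),
  transform = list(rotation = 5, scale = 1.05, translation = c(3, -2)),
  seed = 4)

# register the preoperative vessel map onto the postoperative one
reg <- register_pair(pair$truth$masks$pre$all, pair$truth$masks$post$all)
reg$metrics$success
#> [1] TRUE
round(reg$metrics$overlap, 2); reg$metrics$n_matches
#> [1] 0.99
#> [1] 28

# classify the recipient vessel's flow direction in both videos
pre_dir  <- vessel_flow_direction(pair$pre,  pair$truth$masks$pre$recipient,
                                  tree$centerlines[[1]]$path)
post_dir <- vessel_flow_direction(pair$post, pair$truth$masks$post$recipient,
                                  pair$truth$post_tree$centerlines[[1]]$path)
pre_dir
#> flow direction: forward (confidence 0.99)
post_dir
#> flow direction: middle_to_both_sides (confidence 1.00)
direction_change(pre_dir, post_dir)
#> [1] "changed"
```

The registration metrics say the two acquisitions were matched (99% of
vessel pixels overlap after warping, supported by 28 SIFT
correspondences), and the flow verdicts recover exactly what the generator
encoded: forward flow preoperatively, dye spreading from the anastomosis
to both ends postoperatively — a changed flow direction, the signature of a
patent bypass.

Agreement between two raters of such verdicts over a cohort is
summarised with:

```r
tab <- contingency_table(matrix(c(74, 8, 4, 34), 2), c("forward", "reverse"))
cohen_kappa(tab)
#> Cohen's kappa: 0.775 (substantial agreement)
#>   observed agreement 0.9000, expected 0.5550, n = 120
#>   asymptotic se 0.061, approximate T 8.517
```

A command-line interface wrapping these functions is installed at
`inst/cli/icgflow.R` (subcommands `simulate`, `register`, `flow`,
`perfusion`, `agree`, `ttest`, `run`).

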