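---
title: "Quantifying blood flow in ICG video angiography: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood flow in ICG video angiography: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgflow)
```

## The problem

During superficial temporal artery to middle cerebral artery (STA-MCA)
bypass surgery — the standard revascularisation for moyamoya disease — the
surgeon injects indocyanine green (ICG) and films the cortex under
near-infrared light. Vessels brighten as the dye arrives, so the order and
direction of wash-in encodes the blood-flow pattern: *forward* along the
recipient vessel, *reverse*, or, after a working bypass, *from the
anastomosis towards both ends* ("middle to both sides"). Commercial
microscope software renders a static colour map of relative arrival time;
it cannot report the flow direction inside a single vessel, nor compare
preoperative and postoperative acquisitions taken under different lens
positions and zoom.

`icgflow` implements the full analysis chain needed to do both: vessel
segmentation, registration of the preoperative vessel map onto the
postoperative one, dense optical-flow estimation with a per-vessel
direction verdict, perfusion mapping, and the agreement statistics used to
compare two categorical readings of the same patients. A synthetic video
generator with complete ground truth makes every stage testable without
clinical footage.

## The synthetic generator

`generate_vessel_tree()` draws a branching phantom: one main (recipient)
vessel crossing the frame plus side branches of smaller calibre, each a
smooth random path rasterised with a tapering radius. `generate_icg_video()`
renders wash-in as a logistic brightness ramp at each vessel pixel,

$$I(x, t) = \mathrm{base} + (\mathrm{peak} - \mathrm{base})\,
  \sigma\!\left(\frac{t - a(x)}{\tau}\right) + \varepsilon,$$

with per-pixel arrival time $a(x)$, rise time $\tau$, additive Gaussian
sensor noise $\varepsilon$, and quantisation to 8 bits. The logistic shape
was chosen because it has a genuine plateau, which gives "stable frame"
selection something well-defined to find. Arrival increases with
centreline arc-length for forward flow, decreases for reverse flow, and is
V-shaped around a marked anastomosis point for the middle-to-both-sides
pattern. `generate_pre_post_pair()` warps the same tree by a known
similarity transform (rotation up to 45 degrees, scale 0.5-2, translation)
to emulate microscope repositioning between acquisitions, and returns the
true homography.

Defaults represent a typical acquisition: 25 frames/s, 8-bit intensities
with baseline 20 and peak 180, rise time 0.8 s, dye crossing the tree in
6 s starting 1 s into the video, sensor noise of 2 intensity units. What
the generator deliberately does *not* emulate: tissue background texture,
microscope auto-dimming, dye recirculation, and out-of-plane motion. Tests
passing on this phantom therefore demonstrate algorithmic correctness
under the stated model, not clinical performance.

Throughout the package, matrices are indexed 1-based as `(row, column)`
with `x = column` and `y = row`, R's native convention.

## Vessel segmentation

The segmenter is a multi-task U-Net: a shared contracting encoder (per
level, two 3x3 convolutions with ReLU, then 2x2 max pooling) and two
structurally identical expanding decoders (2x2 up-convolution, skip
concatenation from the matching encoder level, two 3x3 convolutions), one
head for all vessels and one for the recipient vessel, each ending in a 1x1
convolution and a two-class softmax. The joint loss is

$$L = \alpha L_{\mathrm{all}} + \beta L_{\mathrm{receip}},$$

where each term is the mean per-pixel negative log-likelihood of the true
label and $\alpha = \beta = 1$ by default. Normalising per pixel keeps the
weights independent of batch and image size. The loss is implemented with
a positive sign (a proper NLL), which is what minimisation requires.

Training uses Adam, batch 32, 150 iterations, and a stepped learning rate
of 0.01 / 0.001 / 0.0001 switching at iterations 0, 20 and 100. The
training set is expanded four-fold by horizontal, vertical and diagonal
(transpose) flips; at prediction time the network is averaged over five
views — the original, the three flips, and the 180-degree rotation, the
natural fifth involution completing the set — each mapped back before
averaging. Binarisation threshold: 0.5 on the averaged probability.
Inputs whose sides are not divisible by $2^{\mathrm{depth}}$ are
reflection-padded and cropped back.

Channel widths are 8/16/32/64 over the four encoder levels, with the
bottleneck reusing the last width. These widths are a desk-scale choice:
the package trains on a single CPU, and the bright-tube-on-dark-background
task saturates well below larger capacities (held-out all-vessel Dice is
about 0.97-0.99 at the scale used in the acceptance suite: 32 training
images of 64x64, augmented to 128, 150 iterations — roughly four minutes of
CPU time). Narrower nets (4/8/16/32) can collapse to all-background under
the same schedule, so widths are exposed in `seg_config()`. A known
limitation at this scale: the recipient-vessel head learns vesselness but
not reliably branch identity within 150 iterations — its probabilities peak
around 0.35 and threshold to an empty mask. Distinguishing "the widest
branch" evidently needs more optimisation steps than the schedule allows;
the all-vessel head is unaffected. Evaluation uses the Dice coefficient
$2|A \cap B| / (|A| + |B|)$ and Jaccard index $|A \cap B| / |A \cup B|$,
both defined as 1 when both masks are empty.

The 3x3 convolutions (forward and backward) run through fused
im2col + GEMM kernels in C++ (`src/conv.cpp`); everything else, including
the hand-derived backpropagation and Adam, is plain R on BLAS. Gradients
were verified against central finite differences to a relative error of
1e-8.

## Registration

Registration aligns the preoperative segmented vessel map (moving) to the
postoperative one (fixed). Both binary maps are blurred with a Gaussian of
sigma 2 px so the difference-of-Gaussian detector finds structure, then
SIFT keypoints are extracted: DoG extrema over a scale-space pyramid
(3 scales per octave, base sigma 1.6, initial 2x upsampling), subpixel
refinement by a 3D quadratic fit, contrast threshold 0.03 (0.02 inside
`register_pair()`, where blurred binary input guarantees strong contrast),
edge rejection at curvature ratio 10, 36-bin orientation histograms, and
the classical 4x4x8 descriptor with trilinear binning, L2 normalisation
and 0.2 clipping. Matching keeps a correspondence only when the
nearest-neighbour distance is less than 0.8 of the second-nearest
(strictly; a single candidate set has no second neighbour and is
rejected).

The transform is estimated by RANSAC (2000 samples of 4 matches, 3 px
inlier threshold, fixed seed) followed by least-squares refits on the
inlier set with the acceptance threshold annealed from 3 px down to
1.2 px. Three models are available. The default in `register_pair()` is a
*similarity* (rotation + isotropic zoom + translation, fitted in closed
form by Umeyama's method), which is exactly the family of changes a
repositioned, refocused microscope induces and is itself a homography;
full projective and affine fits are available in `estimate_homography()`.
The constrained model matters because matched keypoints cover only the
vessel region: an 8-parameter projective fit absorbs the roughly 1 px
keypoint localisation noise into its perspective terms and extrapolates
poorly towards the frame corners. After the keypoint estimate, the four
similarity parameters are polished by maximising the intensity correlation
of the warped moving map with the fixed map (Nelder-Mead); this removes
the small scale bias introduced by blurring both maps with a *fixed* sigma
across a scale change. On the synthetic transform grid (rotations 0-20
degrees, scales 0.9-1.2) this pipeline recovers the true transform with a
maximum corner reprojection error well under 1 px.

A registration is declared successful when the warped and fixed vessel
masks overlap in at least 35% of the vessel pixels — the denominator being
the smaller of the two vessel areas, the reading we adopt of "overlap of
the vessel pixels" (the union would double-count resolution-dependent
boundary loss) — and at least 10 correspondences support the fit.

## Optical flow and direction classification

Dense motion between consecutive frames is estimated with the
Horn-Schunck variational method: brightness constancy plus a global
smoothness penalty weighted by $\lambda$, solved by Jacobi-style iteration

$$u^{k+1} = \bar u^k - \frac{I_x\,(I_x \bar u^k + I_y \bar v^k + I_t)}
  {\lambda^2 + I_x^2 + I_y^2},$$

with the classical 2x2x2 derivative stencils, zero initial flow, a
four-level Gaussian pyramid solved coarse-to-fine with intermediate
warping, and iteration stopping when the energy functional changes by less
than 0.1 between consecutive iterations (safeguarded at 200 iterations per
level). Two scaling conventions required a decision. First, intensities
enter on the native 8-bit 0-255 scale: $\lambda = 2$ balances the data and
smoothness terms for 8-bit gradients, whereas on unit-scaled images
$\lambda^2 = 4$ would dwarf $I_x^2 + I_y^2 \sim 10^{-3}$ and crush the
data term (empirically, a 2 px shift is then recovered as 0.03 px).
Second, the energy is the discretised integral — a sum over pixels — so the
0.1 threshold is meaningful; on a per-pixel mean it would fire after one
iteration. The denominator uses $\lambda^2$, reading the smoothness weight
as entering squared, consistent with the classical method.

`vessel_flow_direction()` turns flow fields into a verdict. Frames are
taken from the middle of the wash-in — the central half of the interval
between the first crossing of 10% and the last crossing of 90% of the
frame-mean brightness range — because early and late phases have little
brightness change and hence little directional signal. Because the
wash-in front moves less than a pixel per frame while sensor noise is
uncorrelated between frames, the video is first smoothed along time
(moving average, 5 frames) and flow is computed across a 2-frame step;
both are exposed in `direction_config()`. Each vessel pixel's flow vector
is projected onto the local centreline tangent; pixels below the 10th
percentile of flow magnitude do not vote, and votes are weighted by
magnitude. With $s$ the weighted mean vote sign: the verdict is
*middle_to_both_sides* if the arc-length profile of the mean vote changes
sign exactly once, from negative to positive, with both halves beyond 0.3
in magnitude; otherwise *forward* if $s > 0.3$, *reverse* if $s < -0.3$,
else *indeterminate*. The 0.3 threshold and 10-bin profile are exposed in
the configuration; on the synthetic benchmark (30 videos, 10 per
category, sensor noise at the generator default) classification is
typically error-free, and the suite requires at least 27/30.

`direction_change()` compares two verdicts, propagating indeterminacy.
When no centreline is supplied it is traced by Zhang-Suen thinning plus a
double breadth-first search; note that the orientation of an auto-traced
centreline — hence the meaning of forward vs reverse — follows the detected
endpoint order, so supplying an oriented centreline is recommended.

## Perfusion mapping

`luminance_curve()` is the mean ROI brightness per frame against time
(first frame at $t = 0$). `delay_time()` is the time at which the curve
first attains its maximum, after a centred 5-frame moving average (0.2 s
at 25 fps) that stabilises the argmax on noisy input; ties break to the
earliest frame, and a flat curve returns 0 with a warning. The per-pixel
version of the same quantity drives `perfusion_color_map()`: time-to-peak
is mapped linearly onto a red-to-blue-purple ramp between the 1st and 99th
percentiles within the vessel mask (early = red, late = blue-purple),
background black. The commercial look-up table is unknown, so colour
equality with microscope output is out of scope; what is preserved — and
tested — is the ordering: ramp position is a monotone function of
time-to-peak, and along a noiseless synthetic vessel the time-to-peak
ordering reproduces the generator's arrival ordering exactly.
`colorbar_lookup()` inverts a colour to its ramp position by nearest RGB
distance, the digital analogue of reading a colour against the printed
bar. Delay times are measured from the first frame; absolute offsets
against readings measured from injection cancel in the paired differences
the statistics operate on.

## Agreement statistics

`cohen_kappa()` computes $\kappa = (P_o - P_e)/(1 - P_e)$ from a square
contingency table, with the conventional interpretation bands (slight
< 0.2, fair 0.2-0.4, moderate 0.4-0.6, substantial 0.6-0.8, almost
perfect > 0.8), the asymptotic standard error, and the null-hypothesis
z statistic. `percent_agreement()` is the raw diagonal fraction.
`paired_t_test()` wraps the two-sided one-sample t-test on paired
differences, and `normality_check()` provides the numerical content of a
normal Q-Q plot (ordered sample against normal plotting positions, plus
their correlation) as the pre-check. Degenerate inputs — marginals with
expected agreement 1, zero-variance differences — raise errors rather than
returning misleading numbers.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen for a single CPU: direction
classification on 30 videos of 128x128 x 250 frames; registration on 20
vessel maps of 256x256 with 7 branches (yielding 50-80 keypoints each,
approaching the keypoint counts typical of clinical vessel maps);
segmentation training on 32 images of 64x64 augmented four-fold. Clinical
figures reported for the original 120-patient cohort (Dice 0.80,
registration success 81%, 89%/87% direction agreement) are properties of
undeposited data and are not reproduced; the package instead tests the
desk-scale analogues above, plus the exact agreement statistics, which are
computable from the published tables.

## Known limitations

- The recipient-vessel decoder head needs more than the default 150
  iterations to beat the 0.5 threshold (see above).
- Registration assumes a near-planar scene and in-plane microscope motion;
  deformable changes (brain shift, swelling) are out of scope.
- Direction verdicts assume a single dominant vessel per mask; branching
  recipient masks should be analysed per branch.
- Video container decoding (MPG/AVI/MP4) is not available in this R stack;
  `read_video()` accepts numbered PNG sequences and in-memory arrays.
- Flow velocities are reported in px/frame and are not calibrated to
  physical units; only direction is interpreted.
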