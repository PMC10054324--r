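---
title: "Measuring and counting aquatic organisms from stereo video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and counting aquatic organisms from stereo video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereofish)
```

`stereofish` implements the processing chain of a stationary underwater
stereo-video observatory: activity filtering, detection post-processing,
bounding-box stereo correspondence, metric size and distance measurement,
checkerboard validation, and MaxN abundance estimation. This vignette is
the package's account of the models it implements, the parameters that
matter, the numerical choices made, and what its synthetic tests do and do
not demonstrate about real field data.

## Camera model and conventions

Pixel coordinates originate at the top-left image corner, x to the right
and y downward, continuous at pixel centers. 3D coordinates are
millimetres in the left-camera frame: z forward, x right, y down. These
conventions are not universal across imaging software, so they are fixed
here once and used everywhere, including in the synthetic generator.

Each camera is an ideal pinhole (`fx`, `fy`, `cx`, `cy`) extended with the
standard five-coefficient polynomial distortion model on normalized image
coordinates: radial terms k1, k2, k3 and tangential terms p1, p2. All five
coefficients are supported and may be zero — whether tangential terms are
enabled is a property of the upstream calibration toolbox, not of this
package, so the reader accepts any subset. Refraction through a flat
housing port formally breaks the single-viewpoint assumption; like the
observatory practice this package models, we rely on the in-situ
calibration to absorb refraction into the distortion polynomial and accept
the residual systematic error rather than ray-trace the port explicitly.

Undistortion inverts the polynomial by fixed-point iteration on normalized
coordinates: at most 20 iterations to a tolerance of 1e-8 normalized units,
which is deterministic and accurate to well below 1e-6 px for the moderate
distortions typical of calibrated rigs. Non-convergence (a pixel outside
the invertible region of the model) is an error, not a silent result.

A stereo rig is the pair of intrinsics plus the right camera's pose in the
left frame (orthonormal rotation, determinant +1 within 1e-9; translation
with positive norm — 120 mm baseline in the default synthetic rig).
Rectification follows the usual construction: the common rectified x-axis
is the baseline direction, both virtual cameras share one orientation, a
common focal length (the mean of the four input focals) and principal
point. After rectification a scene point projects to equal rows in both
views, correspondence search collapses to the horizontal epipolar line,
and depth is `z = f·B/disparity`. Triangulation averages the two row
coordinates of a correspondence; a row disagreement beyond a configurable
tolerance (default 2 px — the epipolar constraint should hold to sub-pixel
for calibrated data, but detector boxes are noisier than corners) logs a
warning first. Non-positive disparity means a point at infinity or a wrong
match and is rejected outright.

## Synthetic scenes: what they emulate

No public recording exists for this kind of observatory, so the package
carries a generator whose defaults reproduce the documented study
conditions: a 120 mm-baseline monochrome stereo pair at 1280 × 1024 px and
20 fps, a 9 × 8-square checkerboard with 50 mm squares presented at
0.5–2.0 m, and fish/jellyfish targets from a ten-class vocabulary.

Targets are 3D ellipsoids (length × height × width) on piecewise-linear
trajectories. A ground-truth box is the image-axis-aligned hull of 26
sampled surface extremal points — the six axis endpoints exactly, plus
edge/corner directions — which defines precisely what a "box corner" means
in 3D, the quantity the measurement stage inverts. The noisy detection
stream applies, in order: per-corner Gaussian jitter (default 0.5 px),
per-detection dropout, uniformly placed false positives (Poisson per frame
per camera), and optional label confusion. True-positive confidences are
drawn from Beta(8, 2) and false positives from Beta(2, 5); these shapes are
not measurements of any real detector, they simply produce usable
precision–recall curves with overlapping but distinguishable score
distributions.

Rendered frames (for the activity stage) are static background plus
Gaussian pixel noise with targets drawn as filled ellipses. The generator
therefore emulates geometry, occlusion-free visibility, detector noise and
class confusion — it does **not** emulate turbidity, lighting dynamics,
biological shape variation, fish flexion, or correlated detector errors.
Passing tests demonstrate the correctness of the pipeline's mathematics
and logic under controlled noise, not the field performance of any
particular detector.

## Activity detection

Each pixel's intensity history is an online mixture of up to K Gaussians.
A pixel is declared foreground when its median-filtered intensity lies
outside `sqrt(varThreshold)` standard deviations of every
background-weighted component, where the background components are those
covering the top `backgroundRatio` (default 0.9) of the weight mass.
Matched components update their weight, mean and variance at the learning
rate; unexplained intensities replace the weakest component. Defaults
(median kernel 5, K = 5, history 100 frames, varThreshold 16, learning
rate 1/history, fraction threshold 0.001, minimum run 5 frames, merge gap
10) are chosen for recall, because the stage's purpose is to make sure no
animal-bearing segment is discarded; precision is the detector's job
downstream. The stage is optional — in an online deployment the detector
alone is cheaper and more accurate — and the pipeline treats the whole
frame range as one active sequence when it is bypassed.

Run extraction applies three rules in order: threshold the per-frame
foreground fraction, join active runs separated by fewer than `mergeGap`
inactive frames, then drop runs shorter than `minLength`. The result is a
sorted, non-overlapping set of frame intervals.

## Detection post-processing and evaluation

Post-processing applies a confidence floor and class-agnostic greedy NMS:
any detection whose IoU with an already-kept, higher-confidence box is
strictly greater than 0.6 is discarded, whatever its class. The strict
inequality matters at the threshold itself and is tested.

Evaluation ranks each class's detections by confidence and matches them
greedily, one-to-one, to same-class ground truth of the same frame and
camera at IoU ≥ 0.5. Average precision uses all-point (continuous)
interpolation — exact and directly checkable against a brute-force
all-threshold oracle, unlike 11- or 101-point approximations. mAP is the
mean over classes that have ground truth. F1 curves are evaluated on a
0–1 confidence grid with step 0.005, fine enough to resolve optima quoted
to three decimals; the mean F1 is averaged over classes present in the
ground truth.

The confusion matrix adds a background class. Its layout is rows = true
class, columns = predicted class; a second, class-agnostic matching pass
over the leftovers fills the off-diagonal cells (localized but
misclassified), unmatched ground truth lands in the background column of
its class row, and unmatched detections land in the background row of
their predicted column. With this layout the raw-count rows sum exactly to
the per-class ground-truth totals and the background row sums to the total
false positives — the published matrices this mirrors do not state their
matching rule, so conservation was chosen as the defining property, and
both row- and column-normalized views are provided.

## Stereo matching and measurement

For a left/right box pair with centers `(x1, y1)`, `(x2, y2)`:

* `θ = |arctan((y2 − y1)/(x2 − x1))|`, the angle of the center line from
  the horizontal, in degrees;
* `iou`, the intersection over union of the two boxes *in rectified
  coordinates* — overlap between views is only meaningful once rows are
  aligned, so boxes are undistorted, their four corners rectified, and the
  box re-formed as the axis-aligned hull before scoring;
* `mscore = iou/θ`, gated to zero when `θ > θ_thresh`, `iou < iou_thresh`,
  or the predicted classes differ.

Two numerical decisions are documented rather than implied. First, the
score is singular at θ = 0, which is the *ideal* rectified case; it is
evaluated as `iou / max(θ, ε)` with ε = 0.1°, capping the score while
preserving its ordering. Second, θ is measured in degrees; the unit choice
rescales scores uniformly and changes neither the gates nor the ranking,
so it is a convention, not a modeling claim. Defaults θ_thresh = 5°,
iou_thresh = 0.05 are configurable; they gate generously because
rectification already guarantees near-zero θ for true matches.

Candidate pairs are accepted greedily by descending score with one-to-one
use of each detection and a deterministic tie-break (lower left index,
then lower right index). Greedy — rather than optimal-assignment —
resolution matches the "highest matching score" rule the method is built
on; the exhaustive maximum-score-sum assignment is kept as a test oracle,
and on seeded synthetic instances with up to 6 detections per side the two
agree.

Measurement triangulates the four corner correspondences of a matched
pair. Width is the mean 3D length of the top and bottom edges, height of
the left and right edges, and distance the norm of the triangulated
box-center point — a corner-based procedure chosen over center-plus-mean-
disparity because the box corners are the quantities the matcher actually
aligns. Degenerate boxes and non-positive corner disparities reject the
measurement with a logged reason. For fronto-parallel targets the
procedure is exact (noise-free synthetic plates recover their dimensions
to numerical precision); for oblique fish it reports the projected extent,
a known limitation shared by any box-corner method — pose-aware key-point
measurement is out of scope.

## Checkerboard validation

The four-step validation: detect (here: inject) the inner corners of a
9 × 8 board in both views; triangulate each corner; measure the 3D
distance between every corner pair sharing a grid row (horizontal) or
column (vertical) at *all* index gaps k ≥ 1, not only adjacent pairs; and
compare with k × 50 mm. A full 8 × 7 grid yields 196 horizontal and 168
vertical pairs. Per image, horizontal and vertical mean absolute errors
are reported separately, pairs weighted uniformly (the alternative —
weighting by gap — is defensible but was not chosen; uniform is simpler
and reported as such), and the image's recording distance is the mean
triangulated corner depth. Corner *detection* on real images is not a
contribution of this package and sits behind the corner-table interface.

`errorVsDistance()` bins per-image reports by distance. With 0.5 px corner
noise the binned error grows strictly with distance across 0.5/1.0/1.5/2.0
m (50 boards per bin in the acceptance suite) — the expected z²/(f·B)
depth-error scaling. The corresponding field numbers (a few millimetres'
error at these ranges) require the original in-situ calibration imagery
and are not reproduced here; only the noise-free exactness and the
distance trend are asserted. Whether vertical error should exceed
horizontal error (as field data showed) depends on mechanisms the
synthetic model does not capture, so no such assertion is made.

## MaxN abundance

Within one activity sequence, per-frame per-species counts are tallied
from the confidence-filtered, NMS-applied detections of one camera stream
(the left camera by default — which stream feeds counting is a
configuration choice, and counting matched stereo pairs only is available
as an option). MaxN is the maximum single-frame count; ties resolve to the
earliest frame. Aggregation sums sequence-level MaxN values per species
over hours, days or fixed frame intervals; a sequence belongs to the
interval containing its start frame (a deterministic boundary rule chosen
over splitting or end-frame assignment). Re-entering individuals in later
sequences count anew — without re-identification this is unavoidable, and
it is why MaxN under-counts schools: a synthetic school of eight fish with
at most five ever co-visible yields MaxN 5.

## Dataset handling

The VIAME-style track CSV reader validates its invariants (strictly
increasing frames within a track, no duplicate (track, frame) rows,
non-degenerate boxes) and rejects corrupt manifests with line-numbered
errors. Manifest summaries count, per class, the images containing the
class, its boxes and its tracks; the distinct-image total can be smaller
than the per-class sum because one image may host several classes — which
is why published per-class rows reproduce box and track totals exactly but
only bound the image total. The train/validation split is per image
(every box of an image lands in one set), with hard-day holdout forcing
all images of selected recording days into validation before random
sampling fills the training set to the target ratio (default 0.85),
deterministically under a seed. Background images are carried as rows
without annotations so negatives can be included deliberately.

## Problem sizes and determinism

The test and acceptance suites use problem sizes chosen to exercise each
property well inside interactive runtimes: 1000 random points per rig for
geometry round trips, 50 boards per distance bin, 100 seeded matcher
instances, 200 synthetic fish events for size recovery, 5000 boxes for
confusion-rate recovery, and 20 rendered clips at 96 × 80 px for activity
recall — small frames keep the per-pixel mixture model cheap while leaving
blob contrast and geometry representative. Every stochastic step takes an
explicit seed, and all randomness in the pipeline flows from the single
configuration seed; reruns are byte-identical, and the generator restores
the caller's RNG state.

## Known limitations

* Sizes of non-fronto-parallel animals are projected extents, not true
  lengths; pose correction requires key points the box interface does not
  carry.
* The matcher can in principle be fooled by same-class, same-size animals
  on one epipolar line; appearance features are future work by design.
* The activity model has no shadow handling and its hyperparameters are
  exposed rather than tuned, because no reference values exist.
* MaxN is conservative by construction and no population model is layered
  on top of it.
* Calibration estimation (bundle adjustment) is out of scope; the package
  consumes calibration files produced by standard toolboxes.
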