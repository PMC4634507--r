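---
title: "Bilateral asymmetry indices for facial palsy screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral asymmetry indices for facial palsy screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesym)
```

## The measurement model

Facial nerve palsy is almost always unilateral: the affected side of the
face moves less than the healthy side. `facesym` quantifies this from
49-point facial landmark trajectories recorded while the subject performs
three motions — rest, raising the eyebrows, and smiling. Landmark
localization itself (video tracking) is out of scope; the package consumes
per-frame pixel coordinates in a simple trajectory CSV plus a segment
annotation JSON.

For a region $r \in \{\text{forehead}, \text{mouth}\}$ and a side
$s \in \{L, R\}$, a scalar distance $D_s^r(t)$ is measured on every frame
$t$. The motion displacement per side is

$$\rho_s^r = \left| \max_{t \in \text{motion}} D_s^r(t)
  \;-\; \operatorname{mean}_{t \in \text{rest}} D_s^r(t) \right|,$$

where the motion segment is the eyebrow raise for the forehead and the
smile for the mouth, and the rest segment is shared. The asymmetry index is
the ratio with the larger displacement in the denominator,

$$A^r = \frac{\min(\rho_L^r, \rho_R^r)}{\max(\rho_L^r, \rho_R^r)} \in [0, 1],$$

so $A^r = 1$ means perfectly symmetric motion and $A^r = 0$ means total
one-sided paralysis. Because the index is a ratio of distances measured in
the same image, it is invariant to image resolution (global rescaling) and
to in-plane rotation and translation of the head; the test suite asserts
both to $10^{-9}$.

Two geometries are provided for $D_s^r$:

* **Local-points (`region`)** — forehead: distance between the eyebrow
  centroid (P1–P5 left, P6–P10 right) and the eye centroid (P20–P25,
  P26–P31); mouth: mean distance between the mouth corner (P32 left, P38
  right) and the four mouth-midline landmarks (P35, P41, P45, P48).
* **Axis-based (`axis`)** — a horizontal reference line is drawn through
  the medial canthi (P23, P26) and a vertical line perpendicular to it
  through their midpoint (EM); forehead distances are perpendicular drops
  from the brow centroids to the horizontal line, mouth distances are
  perpendicular drops from the corners to the vertical line.

The four pairings of forehead/mouth geometry form the combinations in
`facesym_combos`; `"forehead_region+mouth_axis"` is the default because it
separates classes best on the synthetic cohort, mirroring the relative
ordering reported for clinical data.

### Degenerate and boundary cases

* **Both displacements zero.** A face that does not move on either side is
  symmetric, so the ratio defaults to 1. Set
  `symmetry_ratio(..., zero_rule = "nan")` (or the same flag on
  `extract_features()`) to propagate NaN instead when auditing pipelines.
* **Exact ties** fall through the "otherwise" branch of the ratio and give
  exactly 1, so floating-point ties are stable.
* **Coincident medial canthi** make the reference axes undefined and raise
  a degenerate-geometry error rather than returning nonsense.
* **Axes per frame vs. frozen.** Reference axes are recomputed on every
  frame by default, which is what makes in-plane head drift provably
  harmless (each frame's distances are invariant to its own rigid
  transform). `freeze_axes = TRUE` instead fixes the axes from the mean
  rest shape, for sensitivity analysis; with a motionless head both modes
  agree exactly.

## Classification

Per subject, the feature vector is the pair (forehead index, mouth index).
Two linear classifiers are provided, matching what small clinical cohorts
support:

* `fit_lda()` — two-class LDA in closed form: weights
  $w = \Sigma_{\text{pooled}}^{-1} (\mu_{\text{palsy}} - \mu_{\text{normal}})$,
  bias at the class-mean midpoint shifted by the log prior ratio. Priors
  default to class frequencies (`priors = "equal"` available). When the
  pooled covariance is near-singular (reciprocal condition below
  $10^{-10}$), a ridge of $10^{-8}$ times the mean diagonal is added —
  degenerate toys and two-point training folds remain well-defined without
  affecting regular fits.
* `fit_svm_linear()` — linear-kernel SVM via libsvm (`e1071`), cost
  `c = 1` by default. The fitted hyperplane is surfaced as explicit
  weights/bias with the same sign convention as LDA (positive score =
  palsy).

`loocv()` performs leave-one-out cross-validation and pools one confusion
matrix over all folds (the convention that yields a single
accuracy/precision/recall triple). Palsy is the positive class; the
complementary per-class precision/recall are also reported. A fold whose
training data would be single-class is skipped with a warning and listed in
the report.

## The synthetic cohort generator

No public landmark dataset for facial palsy exists, so the package ships a
generator that emulates the study protocol end to end
(`cohort_spec()` / `generate_cohort()`). Each recording is built from a
mirror-symmetric 49-point template (~100 px inter-ocular distance) through
the 2D shape model $s(p) = s\,R\,(\bar s + \Phi g) + t$: the non-rigid
basis $\Phi$ holds the raise and smile displacement fields, the ramping
coefficients $g$ supply the motion amplitude, and the similarity part
$(s, R, t)$ models per-frame head drift. Palsy is imposed by multiplying
the affected side's motion field by a severity factor in $[0, 1)$; i.i.d.
Gaussian tracker noise is added in image space.

Defaults are fixed once as the study conditions: 13 normal and 23 palsy
subjects; severity uniform on $[0.1, 0.7]$; noise 0.5 px; drift up to 2°
rotation, 3 px translation, 1% scale per frame; 20 rest + 20 frames per
motion segment; raise amplitude 10 px and smile amplitude 8 px. Segment
lengths are far shorter than a clinical 15–20 s video because only the
rest mean and the motion maximum enter the index; amplitudes are plausible
fractions of the inter-ocular distance (no measured excursions are
published for this protocol).

Two template choices are deliberate and worth knowing about:

* **Exact severity identifiability.** The brow centroids sit exactly above
  the eye centroids with a vertical raise field, and the four
  mouth-midline landmarks coincide at the oral centre with a horizontal
  smile field. Every measured distance is then *affine in the motion
  amplitude*, so a noise-free recording with severity $s$ yields an index
  of exactly $s$ under all four geometry combinations — the generator's
  parameter is recoverable to $10^{-9}$, which the acceptance tests
  exploit. With spread midline points the region-based mouth distance is
  strictly convex in the amplitude and the recovered index would carry a
  geometry-dependent bias of order $10^{-3}$; coincident midline points
  trade a little anatomical realism for an exact oracle.
* **Linear ramp.** Motion amplitude ramps linearly to its peak at the last
  frame of each segment. Only the maximum matters for the index, so the
  ramp shape is free; linear keeps per-frame amplitudes analyzable.

What the generator does **not** emulate: correlated tracker noise (real
landmark trackers drift coherently), appearance-driven localization
failures, out-of-plane head motion during a recording, bilateral palsy,
and midline lip landmarks that follow the healthy corner (observed
clinically during asymmetric smiles). Passing tests on this cohort
therefore demonstrate the correctness and noise behaviour of the *index
and classifier machinery*, not clinical performance.

## The head-orientation simulation

`face3d_template()` is a mirror-symmetric, non-planar 3D version of the
face (brow ridge and nose forward of the canthal plane, mouth corners
recessed) with symmetric 3D motion fields; the smile field pulls the
corners outward, slightly up, and *backward* along the cheeks.
`pose_grid()` rotates it (roll = in-plane rotation about the camera axis,
pitch = nodding about the horizontal image axis, yaw = head turn about the
vertical image axis; composition `R_pitch %*% R_yaw %*% R_roll` about the
face centroid, irrelevant for the single-axis sweeps used), projects
orthographically, and runs the standard pipeline. Since the face and its
motion are symmetric, any palsy prediction is purely a projection
artifact. Three properties follow from the geometry and are asserted
exactly:

* **Roll is harmless**: in-plane rotation preserves every distance, so
  indices are constant across the sweep.
* **Pitch is neutral**: rotation about the horizontal axis maps mirror
  pairs to mirror pairs, so the projected face stays symmetric and both
  indices remain exactly 1.
* **Yaw is the failure mode**: with a non-planar face, the backward
  component of the smile adds to the projected displacement of the side
  turning toward the camera and subtracts on the far side, so the mouth
  index decays with |yaw| (about 0.55 at 30°) while the forehead index
  barely moves — the mouth-region measurement is the pose-sensitive one.

The paper-scale experiment trained on 36 real subjects; here the grid
classifier is trained on the synthetic cohort, so the exact angles at
which predictions flip are a property of that training set, not a
reproduction of the clinical boundary.

## Numerical notes and problem sizes

* Distances use plain Euclidean pixel geometry; point-to-line distance is
  the cross-product form $|v_x d_y - v_y d_x|$ with a unit direction
  (normalized at construction, tolerance $10^{-9}$).
* Landmark indices are 1-based externally (P1–P49); files store them
  1-based and frames 0-based with half-open segment ranges.
* "Left"/"right" follow the annotation scheme's index map; every index is
  invariant under a global left/right relabeling (asserted to
  $10^{-12}$ — centroid summation order changes under the swap, so exact
  bit-equality is not expected).
* Test and acceptance workloads are sized for a laptop: 1000 random
  recordings against a straight-line formula oracle, 20 replicate
  36-subject cohorts for the cross-validation stability check, and 61-cell
  single-axis pose sweeps; the full suite runs in well under a minute.

## Known limitations

* Binary screening only (palsy vs. normal); no House–Brackmann grading.
* Eye-region asymmetry is not measured (closing-eye motion is poorly
  captured by landmark displacement; forehead and mouth suffice for the
  binary decision).
* Orthographic projection in the pose study; a perspective camera would
  add a mild distance-dependent term.
* The mouth-axis index inherits the variance of the 2-point canthal line;
  with 0.5 px landmark noise its normal-subject values occasionally dip
  below 0.8, which is the dominant source of cross-validation error on the
  synthetic cohort.
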