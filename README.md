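# facesym

Quantitative screening of facial nerve palsy from facial-landmark
trajectories.

Facial nerve palsy weakens voluntary movement on one side of the face.
Clinical grading (e.g. the House–Brackmann scale) is subjective and varies
between raters; `facesym` provides an objective alternative for anyone who
can supply 49-point facial landmark tracks from video of a subject
performing three motions — rest, raising the eyebrows, and smiling. It is
aimed at biomedical-engineering and clinical-research users building
automated assessment pipelines; landmark tracking itself (any 49-point
tracker derived from the standard 68-point annotation, minus the face
contour) is upstream of this package.

## The statistic

For each facial region (forehead, mouth) and side $s \in \{L, R\}$ a
per-frame distance $D_s(t)$ is measured, with two interchangeable
geometries: *local-points* (brow-centroid to eye-centroid; mouth corner to
lip-midline landmarks) or *axis-based* (perpendicular drops to the
inter-canthal line and to its perpendicular through the eye midpoint). The
side's displacement is

$$\rho_s = \bigl|\max_{\text{motion}} D_s(t) - \text{mean}_{\text{rest}} D_s(t)\bigr|,$$

using the eyebrow-raise segment for the forehead and the smile segment for
the mouth, and the asymmetry index is

$$A = \min(\rho_L, \rho_R) / \max(\rho_L, \rho_R) \in [0, 1],$$

1 for symmetric motion, 0 for total one-sided paralysis. Subjects are
classified palsy vs. normal from the (forehead, mouth) index pair with
closed-form LDA or a linear-kernel SVM under leave-one-out
cross-validation. A 3D simulation module maps how head orientation (roll /
pitch / yaw) distorts the indices under orthographic projection, and a
synthetic cohort generator produces labeled trajectories with controllable
severity, tracker noise and head drift for end-to-end validation.

## Worked example

```r
library(facesym)

# synthetic study cohort: 13 normal + 23 palsy subjects, severity 0.1-0.7,
# 0.5 px landmark noise, mild per-frame head drift
cohort <- generate_cohort(cohort_spec(seed = 1))
tab <- extract_feature_table(cohort, "forehead_region+mouth_axis")
head(tab, 3)
#>   subject_id                      combo forehead_index mouth_index  label
#> 1        n01 forehead_region+mouth_axis          0.959       0.973 normal
#> 2        n02 forehead_region+mouth_axis          0.942       0.983 normal
#> 3        n03 forehead_region+mouth_axis          0.957       0.907 normal

loocv(tab, tab$label, tab$subject_id, "lda", combo = "forehead_region+mouth_axis")
#> <cv_report> lda on forehead_region+mouth_axis: n = 36 folds
#>   confusion (palsy positive): TP 22  FP 0  FN 1  TN 13
#>   accuracy 0.972  precision 1.000  recall 0.957
```

Normal subjects sit near (1, 1); palsy subjects track their severity (a
noise-free recording with attenuation factor 0.4 yields indices of exactly
0.4). One palsy subject with severity near the 0.7 ceiling falls on the
normal side of the LDA boundary; everything else is recovered.

The pose simulation uses the symmetric 3D template face, for which any
palsy call is a pure projection artifact:

```r
clf <- fit_lda(tab, tab$label, combo = "forehead_region+mouth_axis")
g <- pose_grid(face3d_template(), clf, axes = "yaw", angles = -30:30)
min(g$mouth_index)      # 0.552 at |yaw| = 30 degrees
min(g$forehead_index)   # 0.985 - the mouth index is the yaw-sensitive one
plot(g)
```

Roll sweeps leave both indices constant to machine precision and pitch
keeps them at exactly 1 (mirror symmetry survives nodding); yaw is the
orientation that breaks the measurement.

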