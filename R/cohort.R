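# Synthetic landmark-trajectory cohort ------------------------------------
#
# Emulates the study protocol: each subject rests, raises the eyebrows and
# smiles while 49 landmarks are tracked. Normals move symmetrically; palsy
# subjects have the motion of the affected side attenuated by a severity
# factor in [0, 1) (0 = no movement at all). Landmark tracker noise is
# i.i.d. Gaussian per point per frame; head drift is a per-frame similarity
# transform (the 2D rigid+scale shape-model component).

#' Mirror-symmetric 2D face template
#'
#' 49-point neutral face, ~100 px inter-ocular distance, image convention
#' (y down), mirror-symmetric about x = 0. The template is constructed so
#' that the asymmetry index of a noise-free synthetic recording equals the
#' imposed severity factor exactly, under all four geometry combinations:
#' each brow centroid lies exactly above the matching eye centroid and the
#' raise motion is vertical; the four mouth-midline landmarks coincide at the
#' oral centre and the smile motion is horizontal, so every measured distance
#' is affine in the motion amplitude.
#'
#' @return 49 x 2 numeric matrix.
#' @export
face_template_2d <- function() {
  p <- matrix(NA_real_, 49, 2)
  # brows (centroids at x = -/+50, y = 66)
  p[1:5, ]  <- cbind(c(-70, -60, -50, -40, -30), c(68, 65, 64, 65, 68))
  p[6:10, ] <- cbind(c(30, 40, 50, 60, 70),      c(68, 65, 64, 65, 68))
  # nose bridge (midline) and nostril row
  p[11:14, ] <- cbind(0, c(95, 112, 129, 146))
  p[15:19, ] <- cbind(c(-18, -9, 0, 9, 18), c(158, 161, 163, 161, 158))
  # eyes (centroids at x = -/+50, y = 100; medial canthi P23/P26 at -/+30)
  p[20:25, ] <- cbind(c(-70, -60, -40, -30, -40, -60), c(100, 95, 95, 100, 105, 105))
  p[26:31, ] <- cbind(c(30, 40, 60, 70, 60, 40),       c(100, 95, 95, 100, 105, 105))
  # mouth: corners at -/+35; midline landmarks coincide at the oral centre
  p[32, ] <- c(-35, 185)
  p[33:37, ] <- cbind(c(-22, -10, 0, 10, 22), c(181, 183, 185, 183, 181))
  p[38, ] <- c(35, 185)
  p[39:43, ] <- cbind(c(-22, -10, 0, 10, 22), c(189, 191, 185, 191, 189))
  p[44:49, ] <- cbind(c(-15, 0, 15, 15, 0, -15), c(183, 185, 183, 187, 185, 187))
  colnames(p) <- c("x", "y")
  p
}

# Motion displacement fields (49 x 2, pixels at full amplitude).
# Raise: both brows move straight up. Smile: mouth corners move straight
# outward, neighbouring outer-lip points follow at half amplitude.
motion_fields_2d <- function(raise_amp = 10, smile_amp = 8) {
  raise <- matrix(0, 49, 2)
  raise[1:10, 2] <- -raise_amp
  smile <- matrix(0, 49, 2)
  smile[32, 1] <- -smile_amp
  smile[38, 1] <- smile_amp
  smile[c(33, 39), 1] <- -smile_amp / 2
  smile[c(37, 43), 1] <- smile_amp / 2
  list(raise = raise, smile = smile)
}

#' Shape-model parameters (similarity + non-rigid basis)
#'
#' Parameters of the 2D shape model `s(p) = s * R * (base + Phi %*% g) + t`:
#' a similarity transform (scale `s`, in-plane rotation `R`, translation `t`)
#' composed with a non-rigid deformation spanned by a basis `Phi` with
#' coefficients `g`. Identity parameters reproduce the base shape exactly.
#'
#' @param scale positive scalar.
#' @param rotation_deg in-plane rotation, degrees.
#' @param translation length-2 numeric, pixels.
#' @param g numeric coefficient vector over the basis columns (may be empty).
#' @param basis `49 x 2 x length(g)` array of deformation fields (one slice
#'   per coefficient), or `NULL` when `g` is empty.
#' @return A `shape_model_params` list.
#' @export
shape_model_params <- function(scale = 1, rotation_deg = 0,
                               translation = c(0, 0), g = numeric(0),
                               basis = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            length(translation) == 2L, all(is.finite(translation)),
            is.numeric(g))
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (length(g) > 0L) {
    if (is.null(basis) || !(is.array(basis) && length(dim(basis)) == 3L))
      stop("`basis` must be a 49 x 2 x k array when `g` is non-empty",
           call. = FALSE)
    if (dim(basis)[3] != length(g) || dim(basis)[1] != 49L || dim(basis)[2] != 2L)
      stop("basis column count must equal length(g)", call. = FALSE)
  }
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 translation = as.numeric(translation), g = as.numeric(g),
                 basis = basis),
            class = "shape_model_params")
}

#' Apply the 2D shape model to a base shape
#'
#' @param base 49 x 2 numeric matrix (mean shape).
#' @param params a [shape_model_params()].
#' @param frame_index frame index stored on the resulting frame.
#' @return A [landmark_frame()].
#' @export
apply_shape_model <- function(base, params, frame_index = 0L) {
  stopifnot(inherits(params, "shape_model_params"))
  base <- as.matrix(base)
  validate_frame_points(base)
  shape <- base
  for (k in seq_along(params$g))
    shape <- shape + params$g[k] * params$basis[, , k]
  R <- rotation_matrix2(params$rotation_deg)
  out <- params$scale * (shape %*% t(R))
  out <- sweep(out, 2, -params$translation)
  landmark_frame(out, frame_index = frame_index)
}

#' Specification of a synthetic cohort
#'
#' Defaults mirror the study conditions: 13 normal and 23 palsy subjects,
#' palsy severity (affected-side motion attenuation; the noise-free asymmetry
#' index equals it) drawn uniformly from \code{[0.1, 0.7]}, tracker noise 0.5
#' px (i.i.d. Gaussian per point per frame) at the ~100 px inter-ocular
#' template scale, and mild per-frame head drift (2 deg rotation, 3 px
#' translation, 1% scale).
#'
#' @param n_normal,n_palsy subject counts (>= 0).
#' @param severity_range length-2 interval within \code{[0, 1)}.
#' @param affected_side `"left"`, `"right"` or `"random"`.
#' @param noise_sigma landmark noise SD, pixels (>= 0).
#' @param jitter_rot,jitter_trans,jitter_scale per-frame pose jitter bounds:
#'   rotation (degrees), translation (px), fractional scale.
#' @param n_rest,n_motion frames in the rest segment and in each motion
#'   segment.
#' @param raise_amp,smile_amp full motion amplitudes, pixels.
#' @param base_translation face position in the image, pixels.
#' @param fps nominal frame rate (metadata).
#' @param seed integer RNG seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_normal = 13L, n_palsy = 23L,
                        severity_range = c(0.1, 0.7),
                        affected_side = c("random", "left", "right"),
                        noise_sigma = 0.5,
                        jitter_rot = 2, jitter_trans = 3, jitter_scale = 0.01,
                        n_rest = 20L, n_motion = 20L,
                        raise_amp = 10, smile_amp = 8,
                        base_translation = c(270, 380),
                        fps = 30, seed = 1L) {
  affected_side <- match.arg(affected_side)
  stopifnot(n_normal >= 0L, n_palsy >= 0L,
            length(severity_range) == 2L,
            noise_sigma >= 0, jitter_rot >= 0, jitter_trans >= 0,
            jitter_scale >= 0, jitter_scale < 1,
            n_rest >= 1L, n_motion >= 1L, raise_amp > 0, smile_amp > 0,
            length(base_translation) == 2L, fps > 0)
  if (severity_range[1] > severity_range[2] ||
      severity_range[1] < 0 || severity_range[2] >= 1)
    stop("`severity_range` must be an interval within [0, 1)", call. = FALSE)
  structure(
    list(n_normal = as.integer(n_normal), n_palsy = as.integer(n_palsy),
         severity_range = as.numeric(severity_range),
         affected_side = affected_side, noise_sigma = noise_sigma,
         jitter_rot = jitter_rot, jitter_trans = jitter_trans,
         jitter_scale = jitter_scale,
         n_rest = as.integer(n_rest), n_motion = as.integer(n_motion),
         raise_amp = raise_amp, smile_amp = smile_amp,
         base_translation = as.numeric(base_translation),
         fps = as.numeric(fps), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate one synthetic recording
#'
#' Builds a rest / raise / smile trajectory from the 2D template: motion
#' amplitudes ramp linearly from 0 to the full amplitude over each motion
#' segment (peak at the last frame); for palsy subjects the affected side's
#' motion field is attenuated by `severity`. The raise and smile fields form
#' the non-rigid basis of the shape model and the per-frame pose jitter is
#' its similarity part; Gaussian tracker noise is added in image space.
#' Consumes the current RNG stream (seed it, or use [generate_cohort()]).
#'
#' @param spec a [cohort_spec()].
#' @param label `"normal"` or `"palsy"`.
#' @param severity attenuation factor in \code{[0, 1)}; required (and only
#'   used) for palsy. 1 - severity is the fraction of motion lost on the
#'   affected side.
#' @param subject_id identifier string.
#' @param affected `"left"` or `"right"` (palsy only).
#' @return A [recording()].
#' @export
generate_recording <- function(spec, label = c("normal", "palsy"),
                               severity = NA_real_, subject_id = "s01",
                               affected = c("left", "right")) {
  stopifnot(inherits(spec, "cohort_spec"))
  label <- match.arg(label)
  affected <- match.arg(affected)
  if (label == "palsy") {
    if (!is.finite(severity) || severity < 0 || severity >= 1)
      stop("palsy requires a severity factor in [0, 1)", call. = FALSE)
  } else severity <- 1

  fields <- motion_fields_2d(spec$raise_amp, spec$smile_amp)
  if (label == "palsy") {
    side_rows <- if (affected == "left") landmark_pairs[, "left"]
                 else landmark_pairs[, "right"]
    for (nm in names(fields))
      fields[[nm]][side_rows, ] <- severity * fields[[nm]][side_rows, ]
  }
  basis <- array(0, c(49, 2, 2))
  basis[, , 1] <- fields$raise
  basis[, , 2] <- fields$smile

  base <- face_template_2d()
  n <- spec$n_rest + 2L * spec$n_motion
  amp <- cbind(raise = numeric(n), smile = numeric(n))
  ramp <- seq_len(spec$n_motion) / spec$n_motion
  amp[spec$n_rest + seq_len(spec$n_motion), "raise"] <- ramp
  amp[spec$n_rest + spec$n_motion + seq_len(spec$n_motion), "smile"] <- ramp

  pts <- array(NA_real_, c(49, 2, n))
  for (i in seq_len(n)) {
    jit <- shape_model_params(
      scale = 1 + runif(1, -spec$jitter_scale, spec$jitter_scale),
      rotation_deg = runif(1, -spec$jitter_rot, spec$jitter_rot),
      translation = spec$base_translation +
        runif(2, -spec$jitter_trans, spec$jitter_trans),
      g = amp[i, ], basis = basis
    )
    fr <- apply_shape_model(base, jit, frame_index = i - 1L)
    if (spec$noise_sigma > 0)
      fr <- fr + matrix(rnorm(98, sd = spec$noise_sigma), 49, 2)
    pts[, , i] <- fr
  }

  segs <- list(rest  = c(0L, spec$n_rest),
               raise = c(spec$n_rest, spec$n_rest + spec$n_motion),
               smile = c(spec$n_rest + spec$n_motion, n))
  rec <- recording(subject_id, pts, segs, label, fps = spec$fps)
  rec$severity <- severity
  rec$affected <- if (label == "palsy") affected else NA_character_
  rec
}

#' Generate a labeled synthetic cohort
#'
#' Deterministic given `spec` (including `spec$seed`): normals first, then
#' palsy subjects with severities drawn uniformly from `spec$severity_range`
#' and affected sides per `spec$affected_side`.
#'
#' @param spec a [cohort_spec()].
#' @return List of [recording()]s with a `manifest` attribute (data.frame of
#'   subject_id, label, severity, affected side).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_normal + spec$n_palsy
  labels <- c(rep("normal", spec$n_normal), rep("palsy", spec$n_palsy))
  ids <- sprintf("%s%02d", ifelse(labels == "normal", "n", "p"),
                 c(seq_len(spec$n_normal), seq_len(spec$n_palsy)))
  severities <- rep(NA_real_, n)
  sides <- rep(NA_character_, n)
  if (spec$n_palsy > 0L) {
    pal <- which(labels == "palsy")
    severities[pal] <- runif(spec$n_palsy, spec$severity_range[1],
                             spec$severity_range[2])
    sides[pal] <- switch(spec$affected_side,
      random = sample(c("left", "right"), spec$n_palsy, replace = TRUE),
      left = "left", right = "right")
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    recs[[i]] <- if (labels[i] == "palsy")
      generate_recording(spec, "palsy", severities[i], ids[i], sides[i])
    else
      generate_recording(spec, "normal", subject_id = ids[i])
  }
  names(recs) <- ids
  attr(recs, "manifest") <- data.frame(
    subject_id = ids, label = labels, severity = severities,
    affected = sides, stringsAsFactors = FALSE)
  attr(recs, "spec") <- spec
  recs
}
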