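# 3D head-orientation simulation ------------------------------------------
#
# A mirror-symmetric 49-point 3D face with symmetric motion fields is
# rotated (roll = in-plane rotation about the camera z-axis, pitch = nodding
# about the horizontal image x-axis, yaw = head turn about the vertical image
# y-axis), orthographically projected to the image plane, and pushed through
# the same feature extraction and classifier as real recordings. Any palsy
# call on this face is purely a projection artifact; the grid maps which
# head orientations break the method.

#' Construct a mirror-symmetric 3D face
#'
#' @param points 49 x 3 matrix (x, y, z): x right, y down (image convention),
#'   z toward the camera. Must be mirror-symmetric about the x = 0 plane
#'   under the [landmark_pairs] map (tolerance 1e-9) and non-planar (z must
#'   vary).
#' @param raise_field,smile_field 49 x 3 displacement fields at full motion
#'   amplitude, mirror-symmetric like `points`.
#' @return A `face3d` list.
#' @export
face3d <- function(points, raise_field, smile_field) {
  check3 <- function(m, what) {
    m <- as.matrix(m)
    if (!is.numeric(m) || nrow(m) != 49L || ncol(m) != 3L || !all(is.finite(m)))
      stop(what, " must be a finite 49 x 3 matrix", call. = FALSE)
    m
  }
  points <- check3(points, "`points`")
  raise_field <- check3(raise_field, "`raise_field`")
  smile_field <- check3(smile_field, "`smile_field`")
  for (m in list(points, raise_field, smile_field)) {
    l <- m[landmark_pairs[, "left"], , drop = FALSE]
    r <- m[landmark_pairs[, "right"], , drop = FALSE]
    mir <- max(abs(l - cbind(-r[, 1], r[, 2:3])))
    mid <- max(abs(m[landmark_midline, 1]))
    if (mir > 1e-9 || mid > 1e-9)
      stop("face3d must be mirror-symmetric about the x = 0 plane",
           call. = FALSE)
  }
  if (diff(range(points[, 3])) <= 0)
    stop("face3d must be non-planar: z must vary across points", call. = FALSE)
  structure(list(points = points,
                 motion = list(raise = raise_field, smile = smile_field)),
            class = "face3d")
}

#' Built-in symmetric 3D face template
#'
#' The 2D template of [face_template_2d()] extended with a plausible depth
#' profile (brow ridge and nose forward of the canthal plane, mouth corners
#' recessed) and spread mouth-midline landmarks. The raise field moves the
#' brows up with a small outward and forward component; the smile field pulls
#' the mouth corners outward, slightly up and backward along the cheeks. The
#' backward (negative z) smile component is what makes the mouth index
#' yaw-sensitive after projection, while mirror symmetry keeps every index at
#' exactly 1 under pitch.
#'
#' @return A [face3d()].
#' @export
face3d_template <- function() {
  p2 <- face_template_2d()
  # spread the mouth midline vertically (no degeneracy needed here)
  p2[35, ] <- c(0, 178); p2[41, ] <- c(0, 192)
  p2[45, ] <- c(0, 182); p2[48, ] <- c(0, 188)
  z <- numeric(49)
  z[1:10]  <- 6                      # brow ridge
  z[11:14] <- c(8, 11, 14, 17)       # nose bridge
  z[15:19] <- c(8, 12, 14, 12, 8)    # nostril row
  z[20:31] <- 0                      # eyes / canthal plane
  z[c(32, 38)] <- -4                 # mouth corners recessed
  z[c(33:37, 39:43)] <- c(1, 3, 4, 3, 1, 1, 3, 4, 3, 1)
  z[44:49] <- c(2, 3, 2, 2, 3, 2)

  raise <- matrix(0, 49, 3)
  raise[1:5, ]  <- rep(c(-1, -10, 2), each = 5)
  raise[6:10, ] <- rep(c(1, -10, 2), each = 5)
  smile <- matrix(0, 49, 3)
  smile[32, ] <- c(-6, -3, -3)
  smile[38, ] <- c(6, -3, -3)
  smile[c(33, 39), ] <- rep(c(-3, -1.5, -1.5), each = 2)
  smile[c(37, 43), ] <- rep(c(3, -1.5, -1.5), each = 2)
  face3d(cbind(p2, z = z), raise, smile)
}

#' 3D rotation of a point set
#'
#' Right-handed rotations: roll about the z-axis (in-plane), pitch about the
#' x-axis (nodding), yaw about the y-axis (head turn), composed as a single
#' matrix `R = R_pitch %*% R_yaw %*% R_roll` and applied about `center`
#' (default: the centroid of `points`).
#'
#' @param points n x 3 matrix.
#' @param roll,pitch,yaw angles in degrees.
#' @param center length-3 rotation centre.
#' @return n x 3 rotated matrix.
#' @export
rotate3d <- function(points, roll = 0, pitch = 0, yaw = 0,
                     center = colMeans(points)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, all(is.finite(c(roll, pitch, yaw))),
            length(center) == 3L)
  R <- rot3_pitch(pitch) %*% rot3_yaw(yaw) %*% rot3_roll(roll)
  sweep(sweep(points, 2, center) %*% t(R), 2, -center)
}

rot3_roll <- function(a) {  # about z
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot3_pitch <- function(a) { # about x
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot3_yaw <- function(a) {   # about y
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Orthographic projection onto the image plane
#'
#' Drops the z (depth) coordinate.
#'
#' @param points 49 x 3 matrix.
#' @param frame_index stored on the resulting frame.
#' @return A [landmark_frame()].
#' @export
project_face <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 49L, ncol(points) == 3L)
  landmark_frame(points[, 1:2], frame_index = frame_index)
}

#' Synthesize a recording of the rotated 3D face
#'
#' Rest frames are the rotated and projected neutral face; raise and smile
#' frames add the matching motion field ramped linearly from 0 to full
#' amplitude before rotation. The rotation centre is the neutral face
#' centroid throughout, so motion never shifts the pose. The synthesized
#' subject is labeled `"normal"`: with symmetric motion, any palsy prediction
#' is a pure projection artifact.
#'
#' @param face a [face3d()].
#' @param roll,pitch,yaw head orientation, degrees.
#' @param n_rest,n_motion frame counts.
#' @return A [recording()].
#' @export
synthesize_recording <- function(face, roll = 0, pitch = 0, yaw = 0,
                                 n_rest = 5L, n_motion = 5L) {
  stopifnot(inherits(face, "face3d"), n_rest >= 1L, n_motion >= 1L)
  center <- colMeans(face$points)
  n <- n_rest + 2L * n_motion
  pts <- array(NA_real_, c(49, 2, n))
  ramp <- seq_len(n_motion) / n_motion
  shape_at <- function(raise_t, smile_t)
    face$points + raise_t * face$motion$raise + smile_t * face$motion$smile
  k <- 0L
  for (i in seq_len(n_rest)) {
    k <- k + 1L
    pts[, , k] <- rotate3d(shape_at(0, 0), roll, pitch, yaw, center)[, 1:2]
  }
  for (t in ramp) {
    k <- k + 1L
    pts[, , k] <- rotate3d(shape_at(t, 0), roll, pitch, yaw, center)[, 1:2]
  }
  for (t in ramp) {
    k <- k + 1L
    pts[, , k] <- rotate3d(shape_at(0, t), roll, pitch, yaw, center)[, 1:2]
  }
  segs <- list(rest  = c(0L, n_rest),
               raise = c(n_rest, n_rest + n_motion),
               smile = c(n_rest + n_motion, n))
  recording(sprintf("pose_r%+05.1f_p%+05.1f_y%+05.1f", roll, pitch, yaw),
            pts, segs, label = "normal", fps = 30)
}

#' Sweep head orientations and classify the projected face
#'
#' For every cell of the angle grid the symmetric 3D face is rotated,
#' projected, synthesized into a recording, its asymmetry features extracted
#' and classified. Single-axis sweeps hold the other angles at 0; a two-axis
#' sweep forms the full cartesian grid (third angle 0).
#'
#' @param face a [face3d()].
#' @param classifier a fitted `linear_classifier` ([fit_lda()] /
#'   [fit_svm_linear()]).
#' @param axes one or two of `"roll"`, `"pitch"`, `"yaw"`.
#' @param angles numeric grid in degrees, default `-30:30`; values outside
#'   that range trigger a warning but proceed.
#' @param combo geometry combination for feature extraction; defaults to the
#'   classifier's stored combo, falling back to
#'   `"forehead_region+mouth_axis"`.
#' @param n_rest,n_motion frames per synthesized segment.
#' @return A `pose_grid_result` data.frame: angle columns, `forehead_index`,
#'   `mouth_index`, `predicted`.
#' @export
pose_grid <- function(face, classifier, axes = "yaw", angles = -30:30,
                      combo = NULL, n_rest = 5L, n_motion = 5L) {
  stopifnot(inherits(face, "face3d"))
  if (!inherits(classifier, "linear_classifier"))
    stop("`classifier` must be a fitted linear_classifier", call. = FALSE)
  axes <- match.arg(axes, c("roll", "pitch", "yaw"), several.ok = TRUE)
  if (length(axes) > 2L) stop("sweep at most two axes", call. = FALSE)
  if (any(abs(angles) > 30))
    warning("angles outside the -30..30 degree sweep range", call. = FALSE)
  if (is.null(combo))
    combo <- if (!is.na(classifier$combo)) classifier$combo
             else "forehead_region+mouth_axis"

  grid <- if (length(axes) == 1L) stats::setNames(data.frame(angles), axes)
          else expand.grid(angles, angles) |>
            stats::setNames(axes)
  full <- data.frame(roll = 0, pitch = 0, yaw = 0)[rep(1, nrow(grid)), ]
  full[names(grid)] <- grid

  fi <- mi <- numeric(nrow(full))
  for (i in seq_len(nrow(full))) {
    rec <- synthesize_recording(face, full$roll[i], full$pitch[i],
                                full$yaw[i], n_rest, n_motion)
    f <- extract_features(rec, combo)
    fi[i] <- f$forehead_index
    mi[i] <- f$mouth_index
  }
  pred <- predict(classifier,
                  cbind(forehead_index = fi, mouth_index = mi))
  out <- cbind(full, forehead_index = fi, mouth_index = mi,
               predicted = pred, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, axes = axes, combo = canonical_combo(combo),
            class = c("pose_grid_result", "data.frame"))
}

#' Plot a pose-grid result
#'
#' Single-axis sweeps are drawn as index-vs-angle curves; two-axis sweeps as
#' a correct (blue) / wrong (red) classification map — a palsy prediction on
#' the symmetric face counts as wrong.
#'
#' @param x a `pose_grid_result`.
#' @param ... passed to the underlying base graphics call.
#' @return `x`, invisibly.
#' @export
plot.pose_grid_result <- function(x, ...) {
  axes <- attr(x, "axes")
  if (length(axes) == 1L) {
    a <- x[[axes]]
    graphics::plot(a, x$forehead_index, type = "l", col = "steelblue",
                   ylim = range(0, 1, x$forehead_index, x$mouth_index),
                   xlab = paste(axes, "(degrees)"), ylab = "asymmetry index",
                   ...)
    graphics::lines(a, x$mouth_index, col = "firebrick")
    graphics::legend("bottomleft", legend = c("forehead", "mouth"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  } else {
    a1 <- sort(unique(x[[axes[1]]])); a2 <- sort(unique(x[[axes[2]]]))
    z <- matrix(as.numeric(x$predicted == "normal"),
                nrow = length(a1), ncol = length(a2))
    graphics::image(a1, a2, z, col = c("#c03030", "#3060c0"),
                    xlab = paste(axes[1], "(degrees)"),
                    ylab = paste(axes[2], "(degrees)"), ...)
  }
  invisible(x)
}
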