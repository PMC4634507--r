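# Landmark indexing ------------------------------------------------------

#' Index map of the 49-point facial mark-up
#'
#' Landmark indices are 1-based and fixed: points 1-5 left eyebrow, 6-10
#' right eyebrow, 11-19 nose, 20-25 left eye, 26-31 right eye, 32-49 mouth.
#' Named anatomical anchors: P23/P26 left/right medial canthus, P32/P38
#' left/right mouth corner, P35/P41/P45/P48 the mouth midline. "Left" and
#' "right" follow the annotation scheme; every downstream index is symmetric
#' under a global left/right swap, so the choice of side labeling does not
#' affect classification.
#'
#' @format A named list of integer vectors.
#' @export
landmark_groups <- list(
  brow_left          = 1:5,
  brow_right         = 6:10,
  nose               = 11:19,
  eye_left           = 20:25,
  eye_right          = 26:31,
  canthus_left       = 23L,
  canthus_right      = 26L,
  mouth_corner_left  = 32L,
  mouth_corner_right = 38L,
  mouth_midline      = c(35L, 41L, 45L, 48L),
  mouth              = 32:49
)

#' Left/right landmark pairing
#'
#' Two-column integer matrix: row i gives the left-side index and the
#' mirror-matched right-side index. Indices absent from the matrix lie on the
#' facial midline. Used by [swap_sides()], by the synthetic templates (which
#' must be mirror-symmetric) and by the 3D face validator.
#'
#' @format Integer matrix with columns `left`, `right` (20 rows).
#' @export
landmark_pairs <- cbind(
  left  = c(1L, 2L, 3L, 4L, 5L, 15L, 16L, 20L, 21L, 22L, 23L, 24L, 25L,
            32L, 33L, 34L, 39L, 40L, 44L, 49L),
  right = c(10L, 9L, 8L, 7L, 6L, 19L, 18L, 29L, 28L, 27L, 26L, 31L, 30L,
            38L, 37L, 36L, 43L, 42L, 46L, 47L)
)

landmark_midline <- setdiff(1:49, c(landmark_pairs))

# Frames and recordings ---------------------------------------------------

#' Construct a single landmark frame
#'
#' A frame is a 49 x 2 numeric matrix of pixel coordinates (columns `x`,
#' `y`), image convention: y increases downward. Row i is landmark Pi of the
#' 49-point mark-up.
#'
#' @param points 49 x 2 numeric matrix (or object coercible to one); all
#'   coordinates must be finite.
#' @param frame_index integer >= 0, position of the frame in its recording.
#' @return A `landmark_frame`: the validated matrix with a `frame_index`
#'   attribute.
#' @export
landmark_frame <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  validate_frame_points(points)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != 1L || is.na(frame_index) || frame_index < 0L)
    stop("`frame_index` must be a single integer >= 0", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, frame_index = frame_index, class = c("landmark_frame", "matrix", "array"))
}

validate_frame_points <- function(points) {
  if (!is.numeric(points) || !is.matrix(points))
    stop("frame points must be a numeric matrix", call. = FALSE)
  if (nrow(points) != 49L || ncol(points) != 2L)
    stop("a landmark frame needs exactly 49 points with 2 coordinates, got ",
         nrow(points), " x ", ncol(points), call. = FALSE)
  if (!all(is.finite(points)))
    stop("all landmark coordinates must be finite", call. = FALSE)
  invisible(points)
}

#' Swap the left and right landmark groups of a frame
#'
#' Exchanges coordinates between each mirror-matched index pair (e.g. P1 and
#' P10, P23 and P26, P32 and P38) without mirroring the coordinates
#' themselves. Every asymmetry index is invariant under this relabeling.
#'
#' @param frame a [landmark_frame()] or 49 x 2 matrix.
#' @return Matrix of the same shape with sides swapped.
#' @export
swap_sides <- function(frame) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  out <- frame
  out[landmark_pairs[, "left"], ]  <- frame[landmark_pairs[, "right"], ]
  out[landmark_pairs[, "right"], ] <- frame[landmark_pairs[, "left"], ]
  out
}

#' Construct a recording of landmark trajectories
#'
#' Bundles a subject's per-frame landmarks with the frame ranges of the three
#' motions (rest, raise eyebrows, smile) and the subject's class label.
#' Frames are indexed 0..n-1; segments are half-open `[start, end)` ranges on
#' those indices, must be non-empty and pairwise disjoint, and all three
#' labels must be present.
#'
#' @param subject_id character scalar.
#' @param frames list of 49 x 2 matrices/[landmark_frame()]s, or a
#'   `49 x 2 x n` array.
#' @param segments named list with components `rest`, `raise`, `smile`, each
#'   an integer vector `c(start, end)` (half-open, 0-based).
#' @param label `"palsy"` or `"normal"`.
#' @param fps frames per second (metadata only).
#' @return A `recording` object.
#' @export
recording <- function(subject_id, frames, segments, label, fps = 30) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  label <- match.arg(label, c("palsy", "normal"))
  if (is.list(frames)) {
    pts <- vapply(frames, function(f) {
      f <- as.matrix(f)
      validate_frame_points(f)
      f
    }, matrix(0, 49, 2))
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    pts <- frames
    if (dim(pts)[1] != 49L || dim(pts)[2] != 2L)
      stop("frame array must be 49 x 2 x n", call. = FALSE)
    if (!all(is.finite(pts)))
      stop("all landmark coordinates must be finite", call. = FALSE)
  } else stop("`frames` must be a list of 49 x 2 matrices or a 49 x 2 x n array",
              call. = FALSE)
  n <- dim(pts)[3]
  if (n < 1L) stop("a recording needs at least one frame", call. = FALSE)
  segments <- validate_segments(segments, n)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a positive number", call. = FALSE)
  structure(
    list(subject_id = subject_id, points = pts, segments = segments,
         label = label, fps = as.numeric(fps)),
    class = "recording"
  )
}

validate_segments <- function(segments, n_frames) {
  need <- c("rest", "raise", "smile")
  if (!is.list(segments) || !all(need %in% names(segments)))
    stop("`segments` must contain rest, raise and smile ranges", call. = FALSE)
  segments <- segments[need]
  covered <- integer(0)
  for (lab in need) {
    s <- segments[[lab]]
    if (length(s) != 2L || !is.numeric(s) || any(is.na(s)))
      stop("segment '", lab, "' must be c(start, end)", call. = FALSE)
    s <- as.integer(s)
    if (s[1] >= s[2])
      stop("segment '", lab, "' is empty: start must be < end", call. = FALSE)
    if (s[1] < 0L || s[2] > n_frames)
      stop("segment '", lab, "' [", s[1], ", ", s[2],
           ") falls outside the 0..", n_frames - 1L, " frame range", call. = FALSE)
    idx <- s[1]:(s[2] - 1L)
    if (any(idx %in% covered))
      stop("segments must be pairwise disjoint ('", lab, "' overlaps)", call. = FALSE)
    covered <- c(covered, idx)
    segments[[lab]] <- s
  }
  segments
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject", x$subject_id, "-", x$label, "\n")
  cat("  frames:", dim(x$points)[3], "at", x$fps, "fps\n")
  for (lab in names(x$segments))
    cat(sprintf("  %-5s [%d, %d)\n", lab, x$segments[[lab]][1], x$segments[[lab]][2]))
  invisible(x)
}

n_frames <- function(rec) dim(rec$points)[3]

# 1-based frame slice for a segment label
segment_slice <- function(rec, label) {
  s <- rec$segments[[label]]
  if (is.null(s)) stop("recording has no '", label, "' segment", call. = FALSE)
  (s[1] + 1L):s[2]
}

#' Extract one frame from a recording
#'
#' @param rec a [recording()].
#' @param frame_index 0-based frame index.
#' @return A [landmark_frame()].
#' @export
get_frame <- function(rec, frame_index) {
  stopifnot(inherits(rec, "recording"))
  i <- as.integer(frame_index) + 1L
  if (i < 1L || i > n_frames(rec)) stop("frame_index out of range", call. = FALSE)
  landmark_frame(rec$points[, , i], frame_index = frame_index)
}

#' Apply a similarity transform to every frame of a recording
#'
#' Rotates (in-plane, counter-clockwise in x-right / y-down pixel
#' coordinates), scales about the origin and translates all landmarks of all
#' frames by the same transform. Asymmetry indices are invariant under any
#' such transform.
#'
#' @param rec a [recording()].
#' @param scale positive scalar.
#' @param rotation_deg in-plane rotation angle, degrees.
#' @param translation length-2 numeric offset (pixels).
#' @return The transformed [recording()].
#' @export
transform_recording <- function(rec, scale = 1, rotation_deg = 0,
                                translation = c(0, 0)) {
  stopifnot(inherits(rec, "recording"), scale > 0, length(translation) == 2L)
  R <- rotation_matrix2(rotation_deg)
  pts <- rec$points
  for (i in seq_len(dim(pts)[3]))
    pts[, , i] <- sweep(scale * (pts[, , i] %*% t(R)), 2, -translation)
  rec$points <- pts
  rec
}

rotation_matrix2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Plane geometry primitives ----------------------------------------------

#' Arithmetic centroid of a point set
#'
#' @param points n x 2 numeric matrix, n >= 1.
#' @return Length-2 numeric: per-coordinate mean.
#' @export
centroid <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 1L || ncol(points) != 2L)
    stop("`points` must be a non-empty n x 2 matrix", call. = FALSE)
  if (!all(is.finite(points)))
    stop("`points` must be finite", call. = FALSE)
  colMeans(points)
}

#' Euclidean distance between two points
#'
#' @param a,b length-2 numeric coordinates (pixels).
#' @return Non-negative distance.
#' @export
euclidean_dist <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("coordinates must be finite", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Construct a 2D line from a point and a direction
#'
#' @param point length-2 coordinate on the line.
#' @param direction length-2 direction vector (normalized internally; must be
#'   non-zero).
#' @return A `line2d` list with unit `direction`.
#' @export
line2d <- function(point, direction) {
  stopifnot(length(point) == 2L, length(direction) == 2L)
  if (!all(is.finite(point)) || !all(is.finite(direction)))
    stop("line parameters must be finite", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0)
    stop("line direction must be non-zero", call. = FALSE)
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm),
            class = "line2d")
}

#' Line through two distinct points
#'
#' @param p,q length-2 coordinates, p != q.
#' @return A [line2d()].
#' @export
line_through <- function(p, q) {
  d <- q - p
  if (sum(d^2) == 0)
    stop("degenerate geometry: the two points coincide", call. = FALSE)
  line2d(p, d)
}

#' Perpendicular distance from a point to a line
#'
#' Equals the distance from `p` to the foot of its orthogonal projection onto
#' the line.
#'
#' @param p length-2 coordinate.
#' @param line a [line2d()].
#' @return Non-negative distance (pixels).
#' @export
point_line_distance <- function(p, line) {
  if (!inherits(line, "line2d")) stop("`line` must be a line2d", call. = FALSE)
  if (!all(is.finite(p))) stop("`p` must be finite", call. = FALSE)
  v <- p - line$point
  d <- line$direction
  abs(v[1] * d[2] - v[2] * d[1])
}
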