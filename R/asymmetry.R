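# Asymmetry indices ------------------------------------------------------
#
# Two geometries per region:
#  * region (local-points-based): distances between landmark centroids —
#    brow centroid to eye centroid; mouth corner to the mean of the four
#    mouth-midline points.
#  * axis: distances to the face reference axes — the horizontal line through
#    the medial canthi (P23, P26), and its perpendicular through the eye
#    midpoint EM.
# For each side, the displacement is |max over motion frames - mean over rest
# frames| of the relevant distance (raise-eyebrow motion for the forehead,
# smile for the mouth); the asymmetry index is min/max of the two side
# displacements.

#' The four geometry combinations
#'
#' Each combination names the geometry used for the forehead and mouth
#' indices, e.g. `"forehead_region+mouth_axis"`.
#'
#' @format Character vector of length 4.
#' @export
facesym_combos <- c(
  "forehead_axis+mouth_axis",
  "forehead_axis+mouth_region",
  "forehead_region+mouth_axis",
  "forehead_region+mouth_region"
)

parse_combo <- function(combo) {
  key <- gsub("[ _]", "", tolower(combo))
  geoms <- list(
    foreheadaxis_mouthaxis       = c(forehead = "axis",   mouth = "axis"),
    foreheadaxis_mouthregion     = c(forehead = "axis",   mouth = "region"),
    foreheadregion_mouthaxis     = c(forehead = "region", mouth = "axis"),
    foreheadregion_mouthregion   = c(forehead = "region", mouth = "region")
  )
  key2 <- gsub("\\+", "_", key)
  hit <- match(key2, names(geoms))
  if (is.na(hit))
    stop("unknown combo '", combo, "'; expected one of: ",
         paste(facesym_combos, collapse = ", "), call. = FALSE)
  geoms[[hit]]
}

canonical_combo <- function(combo) {
  g <- parse_combo(combo)
  paste0("forehead_", g[["forehead"]], "+mouth_", g[["mouth"]])
}

# Per-frame side distances ------------------------------------------------

#' Brow-to-eye-centre distances (local-points geometry, forehead)
#'
#' Left: distance between the centroid of the left eyebrow (P1-P5) and the
#' centroid of the left eye (P20-P25); right likewise from P6-P10 and
#' P26-P31.
#'
#' @param frame a [landmark_frame()] or 49 x 2 matrix.
#' @return List with `left`, `right` (pixels) and `kind`.
#' @export
brow_eye_distances <- function(frame) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  g <- landmark_groups
  list(
    left  = euclidean_dist(centroid(frame[g$brow_left, ]),
                           centroid(frame[g$eye_left, ])),
    right = euclidean_dist(centroid(frame[g$brow_right, ]),
                           centroid(frame[g$eye_right, ])),
    kind  = "forehead_region"
  )
}

#' Mouth-corner-to-midline distances (local-points geometry, mouth)
#'
#' Left: mean Euclidean distance between the left mouth corner P32 and each
#' of the mouth-midline points P35, P41, P45, P48; right likewise from P38.
#'
#' @inheritParams brow_eye_distances
#' @return List with `left`, `right` (pixels) and `kind`.
#' @export
mouth_corner_distances <- function(frame) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  g <- landmark_groups
  mid <- frame[g$mouth_midline, , drop = FALSE]
  dist_to_mid <- function(corner)
    mean(sqrt((mid[, 1] - corner[1])^2 + (mid[, 2] - corner[2])^2))
  list(
    left  = dist_to_mid(frame[g$mouth_corner_left, ]),
    right = dist_to_mid(frame[g$mouth_corner_right, ]),
    kind  = "mouth_region"
  )
}

#' Face reference axes from the medial canthi
#'
#' The horizontal axis is the extension of the line connecting the left and
#' right medial canthus (P23, P26); the vertical axis is its perpendicular
#' through the eye midpoint EM (midpoint of P23 and P26).
#'
#' @inheritParams brow_eye_distances
#' @return List with [line2d()] components `horizontal` and `vertical`, and
#'   `em`, the eye midpoint.
#' @export
face_axes <- function(frame) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  p23 <- frame[landmark_groups$canthus_left, ]
  p26 <- frame[landmark_groups$canthus_right, ]
  horizontal <- line_through(p23, p26)
  em <- (p23 + p26) / 2
  d <- horizontal$direction
  vertical <- line2d(em, c(-d[2], d[1]))
  list(horizontal = horizontal, vertical = vertical, em = em)
}

#' Brow distances to the horizontal axis (axis geometry, forehead)
#'
#' Perpendicular distance from each eyebrow centroid to the inter-canthal
#' horizontal line — the length of the dropped perpendicular to its foot.
#'
#' @inheritParams brow_eye_distances
#' @param axes optional precomputed [face_axes()] (frozen-axes mode);
#'   default: axes of this frame.
#' @return List with `left`, `right` (pixels) and `kind`.
#' @export
axis_brow_distances <- function(frame, axes = NULL) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  if (is.null(axes)) axes <- face_axes(frame)
  g <- landmark_groups
  list(
    left  = point_line_distance(centroid(frame[g$brow_left, ]), axes$horizontal),
    right = point_line_distance(centroid(frame[g$brow_right, ]), axes$horizontal),
    kind  = "forehead_axis"
  )
}

#' Mouth-corner distances to the vertical axis (axis geometry, mouth)
#'
#' Perpendicular distance from each mouth corner (P32, P38) to the vertical
#' axis through the eye midpoint.
#'
#' @inheritParams axis_brow_distances
#' @return List with `left`, `right` (pixels) and `kind`.
#' @export
axis_mouth_distances <- function(frame, axes = NULL) {
  frame <- as.matrix(frame)
  validate_frame_points(frame)
  if (is.null(axes)) axes <- face_axes(frame)
  g <- landmark_groups
  list(
    left  = point_line_distance(frame[g$mouth_corner_left, ], axes$vertical),
    right = point_line_distance(frame[g$mouth_corner_right, ], axes$vertical),
    kind  = "mouth_axis"
  )
}

# Displacement and ratio ---------------------------------------------------

#' Motion displacement of a distance series
#'
#' Absolute difference between the maximum distance reached during the motion
#' and the mean distance at rest.
#'
#' @param rest_values numeric vector of per-frame distances at rest.
#' @param motion_values numeric vector of per-frame distances during the
#'   motion (raise or smile).
#' @return Non-negative displacement (pixels).
#' @export
displacement <- function(rest_values, motion_values) {
  if (length(rest_values) == 0L || length(motion_values) == 0L)
    stop("rest and motion series must be non-empty", call. = FALSE)
  if (!all(is.finite(rest_values)) || !all(is.finite(motion_values)))
    stop("distance series must be finite", call. = FALSE)
  abs(max(motion_values) - mean(rest_values))
}

#' Bilateral symmetry ratio
#'
#' Ratio of the smaller to the larger of the two side displacements: the
#' larger displacement becomes the denominator, so the index lies in
#' \code{[0, 1]} with 1 = perfect symmetry. When both displacements are zero
#' (no motion on either side) the face is symmetric and the ratio defaults to
#' 1; set `zero_rule = "nan"` to propagate NaN instead for auditing.
#'
#' @param left,right non-negative side displacements (pixels).
#' @param zero_rule `"one"` (default) or `"nan"`: value when both sides are 0.
#' @return Ratio in \code{[0, 1]} (or NaN under `zero_rule = "nan"`).
#' @export
symmetry_ratio <- function(left, right, zero_rule = c("one", "nan")) {
  zero_rule <- match.arg(zero_rule)
  if (!is.finite(left) || !is.finite(right) || left < 0 || right < 0)
    stop("displacements must be finite and non-negative", call. = FALSE)
  if (left == 0 && right == 0)
    return(if (zero_rule == "one") 1.0 else NaN)
  if (left > right) right / left else left / right
}

# Feature extraction -------------------------------------------------------

side_distance_series <- function(rec, frame_idx, region, geometry,
                                 frozen_axes = NULL) {
  fun <- switch(paste(region, geometry, sep = "_"),
    forehead_region = function(f, a) brow_eye_distances(f),
    forehead_axis   = axis_brow_distances,
    mouth_region    = function(f, a) mouth_corner_distances(f),
    mouth_axis      = axis_mouth_distances,
    stop("unknown region/geometry", call. = FALSE)
  )
  out <- matrix(NA_real_, length(frame_idx), 2,
                dimnames = list(NULL, c("left", "right")))
  for (k in seq_along(frame_idx)) {
    d <- fun(rec$points[, , frame_idx[k]], frozen_axes)
    out[k, ] <- c(d$left, d$right)
  }
  out
}

#' Extract the asymmetry feature pair of a recording
#'
#' Computes the forehead and mouth asymmetry indices for one geometry
#' combination. Per frame, the left/right side distances are evaluated over
#' the rest segment and the motion segment paired with the region (raise for
#' forehead, smile for mouth); per side, [displacement()] compares the
#' motion maximum against the rest mean; [symmetry_ratio()] then forms the
#' index.
#'
#' @param rec a [recording()].
#' @param combo one of [facesym_combos] (flexible spelling, e.g. the
#'   `"Forehead_region + Mouth_axis"` form is accepted).
#' @param zero_rule passed to [symmetry_ratio()].
#' @param freeze_axes if `TRUE`, the reference axes are computed once from
#'   the mean rest shape instead of per frame. Per-frame axes (default) make
#'   the indices exactly invariant to in-plane head rotation drift.
#' @return An `asymmetry_features` list: `forehead_index`, `mouth_index`,
#'   `combo`.
#' @export
extract_features <- function(rec, combo = "forehead_region+mouth_axis",
                             zero_rule = c("one", "nan"),
                             freeze_axes = FALSE) {
  stopifnot(inherits(rec, "recording"))
  zero_rule <- match.arg(zero_rule)
  geom <- parse_combo(combo)
  rest_idx  <- segment_slice(rec, "rest")
  raise_idx <- segment_slice(rec, "raise")
  smile_idx <- segment_slice(rec, "smile")

  frozen <- NULL
  if (freeze_axes) {
    mean_rest <- apply(rec$points[, , rest_idx, drop = FALSE], c(1, 2), mean)
    frozen <- face_axes(mean_rest)
  }

  index_for <- function(region, motion_idx) {
    g <- geom[[region]]
    rest   <- side_distance_series(rec, rest_idx,   region, g, frozen)
    motion <- side_distance_series(rec, motion_idx, region, g, frozen)
    symmetry_ratio(
      displacement(rest[, "left"],  motion[, "left"]),
      displacement(rest[, "right"], motion[, "right"]),
      zero_rule = zero_rule
    )
  }

  structure(
    list(
      forehead_index = index_for("forehead", raise_idx),
      mouth_index    = index_for("mouth", smile_idx),
      combo          = canonical_combo(combo)
    ),
    class = "asymmetry_features"
  )
}

#' @export
print.asymmetry_features <- function(x, ...) {
  cat(sprintf("<asymmetry_features> %s: forehead %.4f, mouth %.4f\n",
              x$combo, x$forehead_index, x$mouth_index))
  invisible(x)
}

#' Asymmetry feature table for a set of recordings
#'
#' @param recordings list of [recording()]s.
#' @param combos character vector of geometry combinations (default: all
#'   four).
#' @param ... passed to [extract_features()].
#' @return `data.frame` with columns `subject_id`, `combo`,
#'   `forehead_index`, `mouth_index`, `label` — one row per recording per
#'   combo.
#' @export
extract_feature_table <- function(recordings, combos = facesym_combos, ...) {
  stopifnot(length(recordings) > 0L)
  combos <- vapply(combos, canonical_combo, character(1), USE.NAMES = FALSE)
  rows <- lapply(recordings, function(rec) {
    feats <- lapply(combos, function(cb) extract_features(rec, cb, ...))
    data.frame(
      subject_id     = rec$subject_id,
      combo          = combos,
      forehead_index = vapply(feats, `[[`, numeric(1), "forehead_index"),
      mouth_index    = vapply(feats, `[[`, numeric(1), "mouth_index"),
      label          = rec$label,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
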