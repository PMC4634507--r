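make_frame <- function() {
  fr <- face_template_2d()
  landmark_frame(fr)
}

test_that("brow-eye distances use the 5-point brow and 6-point eye centroids", {
  fr <- matrix(0, 49, 2)
  fr[1:5, ] <- cbind(0:4, 0)                      # left brow centroid (2, 0)
  fr[20:25, ] <- cbind(2, c(5, 6, 7, 5, 6, 7))    # left eye centroid (2, 6)
  fr[6:10, ] <- cbind(100 + 0:4, 0)
  fr[26:31, ] <- cbind(102, c(5, 6, 7, 5, 6, 7))
  d <- brow_eye_distances(fr)
  expect_equal(d$left, 6)
  expect_equal(d$right, 6)
  sym <- sym_recording()
  ds <- brow_eye_distances(sym$points[, , 1])
  expect_identical(ds$left, ds$right)
})

test_that("mouth distances average the four corner-to-midline distances", {
  fr <- matrix(1, 49, 2)
  fr[c(35, 41, 45, 48), ] <- 0                    # midline coincident at origin
  fr[32, ] <- c(-4, 0)
  fr[38, ] <- c(4, 0)
  d <- mouth_corner_distances(fr)
  expect_equal(d$left, 4)
  expect_equal(d$right, 4)

  fr[c(35, 41, 45, 48), ] <- cbind(0, c(1, -1, 0.5, -0.5))
  fr[32, ] <- c(-3, 0)
  d <- mouth_corner_distances(fr)
  expect_equal(d$left, mean(sqrt(c(10, 10, 9.25, 9.25))))
})

test_that("face axes run through the canthi with the perpendicular at EM", {
  fr <- matrix(rnorm(98), 49, 2)
  fr[23, ] <- c(-1, 0); fr[26, ] <- c(1, 0)
  ax <- face_axes(fr)
  expect_equal(ax$em, c(0, 0))
  expect_equal(abs(ax$horizontal$direction), c(1, 0))
  expect_equal(abs(ax$vertical$direction), c(0, 1))

  fr[23, ] <- c(0, 0); fr[26, ] <- c(2, 2)
  ax <- face_axes(fr)
  expect_equal(ax$em, c(1, 1))
  expect_equal(abs(ax$horizontal$direction), c(1, 1) / sqrt(2))
  expect_equal(sum(ax$horizontal$direction * ax$vertical$direction), 0)
  expect_equal(euclidean_dist(ax$em, fr[23, ]), euclidean_dist(ax$em, fr[26, ]))

  fr[26, ] <- fr[23, ]
  expect_error(face_axes(fr), "degenerate|coincide")
})

test_that("axis-based distances drop perpendiculars to the face axes", {
  fr <- matrix(rnorm(98, sd = 0.1), 49, 2)
  fr[23, ] <- c(-1, 0); fr[26, ] <- c(1, 0)
  fr[1:5, ] <- cbind(-2 + rnorm(5, sd = 0.01), -7)  # LEB y = -7 exactly
  fr[1:5, 2] <- -7
  d <- axis_brow_distances(fr)
  expect_equal(d$left, 7)

  fr[23, ] <- c(0, 0); fr[26, ] <- c(2, 2)          # line y = x
  fr[1:5, 1] <- 0; fr[1:5, 2] <- 2
  expect_equal(axis_brow_distances(fr)$left, sqrt(2))

  fr[23, ] <- c(-1, 0); fr[26, ] <- c(1, 0)
  fr[32, ] <- c(-3, 6)
  expect_equal(axis_mouth_distances(fr)$left, 3)
  fr[32, ] <- c(0, 17)                              # on the vertical line
  expect_equal(axis_mouth_distances(fr)$left, 0)
  fr[23, ] <- c(0, 0); fr[26, ] <- c(2, 0)          # EM (1,0), vertical x = 1
  fr[38, ] <- c(4, 5)
  expect_equal(axis_mouth_distances(fr)$right, 3)
})

test_that("displacement is |max(motion) - mean(rest)|", {
  expect_equal(displacement(c(10, 10, 10), c(10, 12, 13)), 3)
  expect_equal(displacement(c(9, 11), 10), 0)
  expect_equal(displacement(10, c(7, 8)), 2)
  expect_error(displacement(numeric(0), 1), "non-empty")
  expect_error(displacement(1, numeric(0)), "non-empty")
})

test_that("symmetry ratio puts the larger displacement in the denominator", {
  expect_equal(symmetry_ratio(3, 4), 0.75)
  expect_equal(symmetry_ratio(4, 3), 0.75)
  expect_identical(symmetry_ratio(5, 5), 1)
  expect_identical(symmetry_ratio(0, 0), 1)
  expect_true(is.nan(symmetry_ratio(0, 0, zero_rule = "nan")))
  expect_equal(symmetry_ratio(0, 2), 0)
  expect_error(symmetry_ratio(-1, 2), "non-negative")
})

test_that("extract_features matches the study geometry end to end", {
  spec <- quiet_spec()
  set.seed(5)
  recn <- generate_recording(spec, "normal")
  for (cb in facesym_combos) {
    f <- extract_features(recn, cb)
    expect_identical(f$forehead_index, 1)
    expect_identical(f$mouth_index, 1)
  }
  set.seed(6)
  recp <- generate_recording(spec, "palsy", severity = 0.5, affected = "left")
  f <- extract_features(recp, "Forehead_region + Mouth_axis") # Table-style name
  expect_equal(f$combo, "forehead_region+mouth_axis")
  expect_equal(f$forehead_index, 0.5, tolerance = 1e-12)
  expect_equal(f$mouth_index, 0.5, tolerance = 1e-12)
  expect_error(extract_features(recp, "forehead_region"), "unknown combo")
})

test_that("indices are invariant to scaling and rigid motion of all frames", {
  set.seed(41)
  for (i in 1:10) {
    rec <- rand_recording()
    base <- vapply(facesym_combos, function(cb) {
      f <- extract_features(rec, cb); c(f$forehead_index, f$mouth_index)
    }, numeric(2))
    k <- runif(1, 0.2, 5)
    scaled <- transform_recording(rec, scale = k)
    rigid <- transform_recording(rec, rotation_deg = runif(1, -180, 180),
                                 translation = runif(2, -500, 500))
    for (tr in list(scaled, rigid)) {
      got <- vapply(facesym_combos, function(cb) {
        f <- extract_features(tr, cb); c(f$forehead_index, f$mouth_index)
      }, numeric(2))
      expect_index_equal(got, base)
    }
  }
})

test_that("indices are invariant under a global left/right relabeling", {
  set.seed(51)
  for (i in 1:10) {
    rec <- rand_recording()
    swapped <- rec
    for (k in seq_len(dim(rec$points)[3]))
      swapped$points[, , k] <- swap_sides(rec$points[, , k])
    for (cb in facesym_combos) {
      a <- extract_features(rec, cb)
      b <- extract_features(swapped, cb)
      # centroid sums run in reversed row order after the swap, so allow
      # float-reassociation slack
      expect_equal(a$forehead_index, b$forehead_index, tolerance = 1e-12)
      expect_equal(a$mouth_index, b$mouth_index, tolerance = 1e-12)
    }
  }
})

test_that("extract_features agrees with the straight-line oracle", {
  set.seed(61)
  for (i in 1:25) {
    rec <- rand_recording()
    for (cb in facesym_combos) {
      f <- extract_features(rec, cb)
      o <- oracle_extract(rec, cb)
      expect_index_equal(c(f$forehead_index, f$mouth_index), o)
    }
  }
})

test_that("frozen axes change results only when the head drifts", {
  spec <- quiet_spec()
  set.seed(71)
  rec <- generate_recording(spec, "palsy", severity = 0.3, affected = "right")
  a <- extract_features(rec, "forehead_axis+mouth_axis")
  b <- extract_features(rec, "forehead_axis+mouth_axis", freeze_axes = TRUE)
  expect_equal(a$forehead_index, b$forehead_index, tolerance = 1e-12)
  expect_equal(a$mouth_index, b$mouth_index, tolerance = 1e-12)
})

test_that("feature tables carry one row per recording per combo", {
  co <- generate_cohort(cohort_spec(n_normal = 2, n_palsy = 3, seed = 9,
                                    n_rest = 5, n_motion = 5))
  tab <- extract_feature_table(co)
  expect_equal(nrow(tab), 5 * 4)
  expect_setequal(unique(tab$combo), facesym_combos)
  expect_true(all(tab$forehead_index >= 0 & tab$forehead_index <= 1))
  expect_true(all(tab$mouth_index >= 0 & tab$mouth_index <= 1))
})
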