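# Test helpers: an independent straight-line oracle for the asymmetry
# indices, an independent closed-form LDA, and random fixture builders.
# The oracle deliberately avoids every package geometry helper: distances,
# perpendicular feet and ratios are spelled out with raw arithmetic.

# Straight-line recomputation of the forehead/mouth indices.
oracle_extract <- function(rec, combo) {
  geom <- list(
    "forehead_axis+mouth_axis"     = c("axis", "axis"),
    "forehead_axis+mouth_region"   = c("axis", "region"),
    "forehead_region+mouth_axis"   = c("region", "axis"),
    "forehead_region+mouth_region" = c("region", "region")
  )[[combo]]

  nrm <- function(v) sqrt(v[1]^2 + v[2]^2)

  frame_vals <- function(P) {
    LEB <- c(mean(P[1:5, 1]), mean(P[1:5, 2]))
    REB <- c(mean(P[6:10, 1]), mean(P[6:10, 2]))
    LEC <- c(mean(P[20:25, 1]), mean(P[20:25, 2]))
    REC <- c(mean(P[26:31, 1]), mean(P[26:31, 2]))
    p23 <- P[23, ]; p26 <- P[26, ]
    u <- (p26 - p23) / nrm(p26 - p23)
    em <- (p23 + p26) / 2
    v <- c(-u[2], u[1])
    perp_h <- function(q) {        # distance to horizontal line via its foot
      foot <- p23 + sum((q - p23) * u) * u
      nrm(q - foot)
    }
    perp_v <- function(q) {        # distance to vertical line via its foot
      foot <- em + sum((q - em) * v) * v
      nrm(q - foot)
    }
    mouth_mid <- P[c(35, 41, 45, 48), , drop = FALSE]
    mean_mid <- function(corner)
      mean(apply(mouth_mid, 1, function(m) nrm(corner - m)))
    list(
      f_region = c(nrm(LEB - LEC), nrm(REB - REC)),
      f_axis   = c(perp_h(LEB), perp_h(REB)),
      m_region = c(mean_mid(P[32, ]), mean_mid(P[38, ])),
      m_axis   = c(perp_v(P[32, ]), perp_v(P[38, ]))
    )
  }

  idx <- function(seg) (rec$segments[[seg]][1] + 1):rec$segments[[seg]][2]
  vals <- lapply(seq_len(dim(rec$points)[3]),
                 function(i) frame_vals(rec$points[, , i]))

  ratio_eq <- function(key, motion_seg) {
    rest <- t(vapply(vals[idx("rest")], `[[`, numeric(2), key))
    mot  <- t(vapply(vals[idx(motion_seg)], `[[`, numeric(2), key))
    rl <- abs(max(mot[, 1]) - mean(rest[, 1]))
    rr <- abs(max(mot[, 2]) - mean(rest[, 2]))
    if (rl == 0 && rr == 0) return(1)
    if (rl > rr) rr / rl else rl / rr
  }

  c(forehead = ratio_eq(paste0("f_", geom[1]), "raise"),
    mouth    = ratio_eq(paste0("m_", geom[2]), "smile"))
}

# Independent two-class LDA (explicit scatter sums, hand-coded 2x2 inverse).
oracle_lda <- function(x, y) {
  inv2 <- function(S) {
    d <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / d
  }
  m0 <- colMeans(x[y == "normal", , drop = FALSE])
  m1 <- colMeans(x[y == "palsy", , drop = FALSE])
  n0 <- sum(y == "normal"); n1 <- sum(y == "palsy")
  sc <- matrix(0, 2, 2)
  for (cl in c("normal", "palsy")) {
    xc <- scale(x[y == cl, , drop = FALSE], scale = FALSE)
    sc <- sc + t(xc) %*% xc
  }
  S <- sc / (n0 + n1 - 2)
  k <- tryCatch(kappa(S, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k <= 0 || 1 / k < 1e-10)
    S <- S + diag(2) * 1e-8 * max(mean(diag(S)), .Machine$double.eps)
  w <- drop(inv2(S) %*% (m1 - m0))
  b <- -sum(w * (m0 + m1) / 2) + log(n1 / n0)
  list(weights = w, bias = b,
       predict = function(xn) ifelse(drop(xn %*% w) + b > 0, "palsy", "normal"))
}

# Random valid recording: arbitrary cloud per frame (plus a common drift so
# frames differ), random segment layout. Uses the current RNG stream.
rand_recording <- function(n_rest = 3L, n_motion = 3L) {
  base <- matrix(runif(98, -100, 100), 49, 2)
  n <- n_rest + 2L * n_motion
  pts <- array(NA_real_, c(49, 2, n))
  for (i in seq_len(n))
    pts[, , i] <- base + matrix(rnorm(98, sd = 4), 49, 2)
  recording("rand", pts,
            list(rest = c(0L, n_rest),
                 raise = c(n_rest, n_rest + n_motion),
                 smile = c(n_rest + n_motion, n)),
            label = "normal")
}

# Mirror-symmetric recording with genuine symmetric motion: left half and
# midline are random, the right half is the exact mirror; rest noise is
# mirrored too, so left/right distances are bit-identical.
sym_recording <- function(n_rest = 3L, n_motion = 3L) {
  half <- matrix(NA_real_, 49, 2)
  half[landmark_pairs[, "left"], ] <-
    cbind(runif(20, -100, -5), runif(20, 0, 200))
  mid <- setdiff(1:49, c(landmark_pairs))
  half[mid, ] <- cbind(0, runif(length(mid), 0, 200))
  mirror <- function(P) {
    P[landmark_pairs[, "right"], ] <-
      cbind(-P[landmark_pairs[, "left"], 1], P[landmark_pairs[, "left"], 2])
    P
  }
  raise <- matrix(0, 49, 2); raise[1:5, 2] <- -runif(1, 5, 12)
  smile <- matrix(0, 49, 2); smile[32, 1] <- -runif(1, 4, 10)
  n <- n_rest + 2L * n_motion
  pts <- array(NA_real_, c(49, 2, n))
  ramp <- seq_len(n_motion) / n_motion
  for (i in seq_len(n)) {
    P <- half + cbind(c(0), matrix(rnorm(49, sd = 0.5), 49, 1)) # y-noise only
    P[landmark_pairs[, "left"], 1] <-
      P[landmark_pairs[, "left"], 1] + rnorm(20, sd = 0.5)      # mirrored below
    if (i > n_rest && i <= n_rest + n_motion)
      P <- P + ramp[i - n_rest] * raise
    if (i > n_rest + n_motion)
      P <- P + ramp[i - n_rest - n_motion] * smile
    pts[, , i] <- mirror(P)
  }
  recording("sym", pts,
            list(rest = c(0L, n_rest),
                 raise = c(n_rest, n_rest + n_motion),
                 smile = c(n_rest + n_motion, n)),
            label = "normal")
}

# Noise-free spec for exact-recovery checks.
quiet_spec <- function(...) {
  cohort_spec(noise_sigma = 0, jitter_rot = 0, jitter_trans = 0,
              jitter_scale = 0, ...)
}

expect_index_equal <- function(a, b, tol = 1e-9) {
  expect_true(all(abs(a - b) <= tol),
              label = sprintf("max index deviation %.3g", max(abs(a - b))))
}
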