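test_that("LDA separates a 1D-embedded toy at the class midpoint", {
  x <- rbind(c(0, 0.5), c(0.1, 0.5), c(1.0, 0.5), c(1.1, 0.5))
  y <- c("normal", "normal", "palsy", "palsy")
  clf <- fit_lda(x, y)
  # boundary crossing along the informative coordinate (y fixed at 0.5)
  x_star <- -(clf$bias + clf$weights[2] * 0.5) / clf$weights[1]
  expect_equal(x_star, 0.55, tolerance = 1e-8)
  expect_identical(predict(clf, rbind(c(0.3, 0.5))), "normal")
  expect_identical(predict(clf, rbind(c(0.9, 0.5))), "palsy")
})

test_that("LDA rejects degenerate inputs", {
  x <- rbind(c(0, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_error(fit_lda(x, c("normal", "normal", "palsy", "palsy")),
               "identical class means")
  expect_error(fit_lda(x, rep("palsy", 4)), "both classes")
})

test_that("LDA weights match the closed-form pooled-covariance solution", {
  set.seed(101)
  for (i in 1:10) {
    n <- 20
    x <- rbind(matrix(rnorm(2 * n, mean = 0.9, sd = 0.08), ncol = 2),
               matrix(rnorm(2 * n, mean = 0.5, sd = 0.12), ncol = 2))
    y <- rep(c("normal", "palsy"), each = n)
    clf <- fit_lda(x, y)
    ora <- oracle_lda(x, y)
    expect_equal(clf$weights, ora$weights, tolerance = 1e-8)
    expect_equal(clf$bias, ora$bias, tolerance = 1e-8)
  }
})

test_that("LDA direction agrees with MASS::lda up to scale", {
  skip_if_not_installed("MASS")
  set.seed(103)
  x <- rbind(matrix(rnorm(60, 1, 0.1), ncol = 2),
             matrix(rnorm(60, 0.6, 0.15), ncol = 2))
  y <- rep(c("normal", "palsy"), each = 30)
  clf <- fit_lda(x, y)
  m <- MASS::lda(x, grouping = y)
  ratio <- clf$weights / drop(m$scaling)
  expect_equal(ratio[1], ratio[2], tolerance = 1e-6)
  expect_identical(predict(clf, x), as.character(predict(m, x)$class))
})

test_that("linear SVM finds the maximum-margin vertical boundary", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("normal", "normal", "palsy", "palsy")
  clf <- fit_svm_linear(x, y)
  expect_lt(abs(clf$weights[2] / clf$weights[1]), 1e-6)
  x_star <- -clf$bias / clf$weights[1]
  expect_equal(x_star, 0.5, tolerance = 1e-6)
  expect_identical(predict(clf, x), y)
  # label swap flips the hyperplane orientation
  clf2 <- fit_svm_linear(x, c("palsy", "palsy", "normal", "normal"))
  expect_equal(clf2$weights, -clf$weights, tolerance = 1e-6)
  expect_error(fit_svm_linear(x, rep("normal", 4)), "both classes")
})

test_that("SVM is deterministic and respects the cost parameter", {
  set.seed(107)
  x <- rbind(matrix(rnorm(40, 1, 0.15), ncol = 2),
             matrix(rnorm(40, 0.5, 0.15), ncol = 2))
  y <- rep(c("normal", "palsy"), each = 20)
  a <- fit_svm_linear(x, y, c = 1)
  b <- fit_svm_linear(x, y, c = 1)
  expect_identical(a$weights, b$weights)
  expect_identical(a$bias, b$bias)
  big <- fit_svm_linear(x, y, c = 100)
  expect_false(isTRUE(all.equal(a$weights, big$weights)))
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  m <- metrics(8, 1, 2, 5)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)
  perfect <- metrics(10, 0, 0, 6)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1))
  expect_warning(m0 <- metrics(0, 0, 3, 5), "precision undefined")
  expect_true(is.nan(m0$precision))
  expect_error(metrics(-1, 0, 0, 2), "non-negative")
  named <- metrics(c(tp = 8, fp = 1, fn = 2, tn = 5))
  expect_equal(named$accuracy, 13 / 16)
})

test_that("LOOCV folds enumerate like an independent closed-form LDA", {
  x <- rbind(c(0, 0.5), c(0.1, 0.55), c(0.2, 0.45),
             c(1.0, 0.5), c(1.1, 0.55), c(0.15, 0.5))
  y <- c("normal", "normal", "normal", "palsy", "palsy", "palsy")
  rep <- loocv(x, y, method = "lda")
  # fold-by-fold oracle
  expected <- vapply(1:6, function(i)
    oracle_lda(x[-i, ], y[-i])$predict(rbind(x[i, ])), character(1))
  expect_identical(rep$per_fold$predicted, expected)
  expect_identical(expected,
                   c("normal", "palsy", "palsy", "palsy", "palsy", "normal"))
  expect_equal(rep$accuracy, 0.5)
  expect_equal(sum(rep$confusion), 6)
})

test_that("LOOCV is perfect on separated data and order-invariant", {
  set.seed(113)
  x <- rbind(matrix(runif(20, 0.9, 1.0), ncol = 2),
             matrix(runif(20, 0.2, 0.5), ncol = 2))
  y <- rep(c("normal", "palsy"), each = 10)
  ids <- sprintf("id%02d", 1:20)
  rep1 <- loocv(x, y, ids, "lda")
  expect_equal(rep1$accuracy, 1)
  perm <- sample(20)
  rep2 <- loocv(x[perm, ], y[perm], ids[perm], "lda")
  expect_equal(rep2$confusion, rep1$confusion)
  expect_equal(rep2$accuracy, rep1$accuracy)
  # LDA and linear SVM agree when classes are well separated
  rep3 <- loocv(x, y, ids, "svm_linear")
  expect_identical(rep3$per_fold$predicted, rep1$per_fold$predicted)
})

test_that("LOOCV skips folds whose training data has one class", {
  x <- rbind(c(0, 0.4), c(0.1, 0.5), c(1, 0.5))
  y <- c("normal", "normal", "palsy")
  w <- capture_warnings(rep <- loocv(x, y, method = "lda"))
  expect_match(w, "single class", all = FALSE)
  expect_equal(rep$n, 2)
  expect_length(rep$skipped_folds, 1)
  expect_equal(sum(rep$confusion), 2)
})

test_that("report metrics stay consistent with the per-fold predictions", {
  co <- generate_cohort(cohort_spec(n_normal = 5, n_palsy = 7, seed = 19,
                                    n_rest = 5, n_motion = 5))
  tab <- extract_feature_table(co, "forehead_region+mouth_axis")
  for (m in c("lda", "svm_linear")) {
    rep <- loocv(tab, tab$label, tab$subject_id, m)
    tp <- sum(rep$per_fold$truth == "palsy" & rep$per_fold$predicted == "palsy")
    fp <- sum(rep$per_fold$truth == "normal" & rep$per_fold$predicted == "palsy")
    fn <- sum(rep$per_fold$truth == "palsy" & rep$per_fold$predicted == "normal")
    tn <- sum(rep$per_fold$truth == "normal" & rep$per_fold$predicted == "normal")
    expect_equal(rep$confusion, c(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_equal(rep$accuracy, (tp + tn) / nrow(rep$per_fold))
    expect_equal(rep$recall, tp / (tp + fn))
  }
})
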