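# Two-class linear classifiers over (forehead_index, mouth_index) ----------

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    stopifnot(all(c("forehead_index", "mouth_index") %in% names(features)))
    x <- as.matrix(features[, c("forehead_index", "mouth_index")])
  } else {
    x <- as.matrix(features)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  x
}

check_labels <- function(y, n) {
  y <- as.character(y)
  if (length(y) != n) stop("one label per feature row is required", call. = FALSE)
  if (!all(y %in% c("palsy", "normal")))
    stop("labels must be 'palsy' or 'normal'", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  y
}

new_linear_classifier <- function(weights, bias, method, combo = NA_character_) {
  structure(
    list(weights = as.numeric(weights), bias = as.numeric(bias),
         method = method, combo = combo, positive = "palsy"),
    class = "linear_classifier"
  )
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf("<linear_classifier> %s: score = %s + %.4g (positive class: %s)\n",
              x$method,
              paste(sprintf("%.4g*x%d", x$weights, seq_along(x$weights)),
                    collapse = " + "),
              x$bias, x$positive))
  invisible(x)
}

#' Fit two-class linear discriminant analysis
#'
#' Closed-form LDA for the palsy/normal decision: the weight vector is the
#' pooled within-class covariance inverse applied to the class-mean
#' difference (palsy minus normal), and the bias places the boundary at the
#' midpoint of the class means, shifted by the log prior ratio. When the
#' pooled covariance is near-singular a small ridge (1e-8 times the mean
#' diagonal) is added.
#'
#' @param features numeric matrix (n x p) or data.frame with
#'   `forehead_index`, `mouth_index` columns.
#' @param labels character vector of `"palsy"` / `"normal"`, both present.
#' @param priors `"frequency"` (class frequencies, default) or `"equal"`.
#' @param combo optional combination name stored on the classifier.
#' @return A `linear_classifier` with `weights`, `bias`, `method = "lda"`.
#'   Scores `x . w + b > 0` predict palsy.
#' @export
fit_lda <- function(features, labels, priors = c("frequency", "equal"),
                    combo = NA_character_) {
  priors <- match.arg(priors)
  x <- feature_matrix(features)
  y <- check_labels(labels, nrow(x))

  x0 <- x[y == "normal", , drop = FALSE]
  x1 <- x[y == "palsy", , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  if (isTRUE(all.equal(mu0, mu1, tolerance = 0)))
    stop("degenerate data: identical class means give no separating direction",
         call. = FALSE)

  sc0 <- if (n0 > 1L) (n0 - 1L) * cov(x0) else matrix(0, ncol(x), ncol(x))
  sc1 <- if (n1 > 1L) (n1 - 1L) * cov(x1) else matrix(0, ncol(x), ncol(x))
  s <- if (n0 + n1 > 2L) (sc0 + sc1) / (n0 + n1 - 2L)
       else matrix(0, ncol(x), ncol(x))   # two singletons: ridge carries it

  if (!all(is.finite(s)) || rcond_sym(s) < 1e-10)
    diag(s) <- diag(s) + 1e-8 * max(mean(diag(s)), .Machine$double.eps)

  w <- tryCatch(solve(s, mu1 - mu0), error = function(e)
    stop("pooled covariance is singular even after regularization", call. = FALSE))
  if (all(w == 0))
    stop("degenerate data: LDA weights are all zero", call. = FALSE)

  p1 <- if (priors == "equal") 0.5 else n1 / (n0 + n1)
  bias <- -sum(w * (mu0 + mu1) / 2) + log(p1 / (1 - p1))
  new_linear_classifier(w, bias, "lda", combo)
}

rcond_sym <- function(s) {
  d <- tryCatch(svd(s, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
  if (max(d) <= 0) return(0)
  min(d) / max(d)
}

#' Fit a linear-kernel support vector machine
#'
#' Maximum-margin linear boundary with hinge-loss cost `c`, fitted with
#' \pkg{e1071} (libsvm). The fitted hyperplane is exposed as explicit
#' `weights` and `bias` with the same orientation convention as [fit_lda()]:
#' positive scores predict palsy.
#'
#' @inheritParams fit_lda
#' @param c regularization strength (libsvm `cost`), default 1.
#' @return A `linear_classifier` with `method = "svm_linear"`.
#' @export
fit_svm_linear <- function(features, labels, c = 1, combo = NA_character_) {
  x <- feature_matrix(features)
  y <- check_labels(labels, nrow(x))
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  yf <- factor(y, levels = c("normal", "palsy"))
  fit <- e1071::svm(x = x, y = yf, kernel = "linear", cost = c,
                    scale = FALSE, type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # align sign so that score > 0 <=> libsvm predicts "palsy"
  ref <- as.character(predict(fit, x))
  score <- drop(x %*% w) + b
  agree <- mean((score > 0) == (ref == "palsy"))
  if (agree < 0.5) { w <- -w; b <- -b }
  if (all(w == 0))
    stop("degenerate data: SVM weights are all zero", call. = FALSE)
  new_linear_classifier(w, b, "svm_linear", combo)
}

#' Predict class labels from a linear classifier
#'
#' @param object a `linear_classifier` from [fit_lda()] or
#'   [fit_svm_linear()].
#' @param newdata feature matrix or data.frame (see [fit_lda()]).
#' @param ... unused.
#' @return Character vector of `"palsy"` / `"normal"`.
#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (ncol(x) != length(object$weights))
    stop("feature dimension mismatch", call. = FALSE)
  score <- drop(x %*% object$weights) + object$bias
  ifelse(score > 0, "palsy", "normal")
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision and recall from TP/FP/FN/TN counts; palsy is the
#' positive class throughout the package. Undefined ratios (zero
#' denominators) are returned as NaN with a warning.
#'
#' @param tp,fp,fn,tn non-negative counts; alternatively pass a single named
#'   vector/list as `tp`.
#' @return List with `accuracy`, `precision`, `recall`.
#' @export
metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    cm <- unlist(tp)
    if (!all(c("tp", "fp", "fn", "tn") %in% names(cm)))
      stop("confusion vector must be named tp/fp/fn/tn", call. = FALSE)
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning NaN", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  list(
    accuracy  = (tp + tn) / total,
    precision = ratio(tp, tp + fp, "precision"),
    recall    = ratio(tp, tp + fn, "recall")
  )
}

#' Leave-one-out cross-validation
#'
#' Each subject is predicted by a classifier trained on all other subjects;
#' the confusion matrix and metrics are pooled once over all folds (palsy
#' positive). Folds whose training data would contain a single class are
#' skipped with a warning and listed in the report. Per-class precision and
#' recall are reported for both conventions.
#'
#' @inheritParams fit_lda
#' @param subject_ids optional identifiers, one per row.
#' @param method `"lda"` or `"svm_linear"`.
#' @param ... passed to the fitting function (`priors`, `c`, ...).
#' @return A `cv_report`: `per_fold` data.frame (subject_id, truth,
#'   predicted), `confusion` (tp/fp/fn/tn), `accuracy`, `precision`,
#'   `recall`, per-class breakdown, `skipped_folds`, `method`, `combo`.
#' @export
loocv <- function(features, labels, subject_ids = NULL,
                  method = c("lda", "svm_linear"), combo = NA_character_, ...) {
  method <- match.arg(method)
  x <- feature_matrix(features)
  y <- check_labels(labels, nrow(x))
  n <- nrow(x)
  if (n < 3L) stop("LOOCV needs at least 3 rows", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%02d", seq_len(n))
  fit_fun <- switch(method, lda = fit_lda, svm_linear = fit_svm_linear)

  predicted <- rep(NA_character_, n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning("fold for subject ", subject_ids[i],
              " skipped: training data has a single class", call. = FALSE)
      skipped <- c(skipped, subject_ids[i])
      next
    }
    clf <- fit_fun(x[-i, , drop = FALSE], ytr, ...)
    predicted[i] <- predict(clf, x[i, , drop = FALSE])
  }

  used <- !is.na(predicted)
  tp <- sum(y == "palsy"  & predicted == "palsy",  na.rm = TRUE)
  fp <- sum(y == "normal" & predicted == "palsy",  na.rm = TRUE)
  fn <- sum(y == "palsy"  & predicted == "normal", na.rm = TRUE)
  tn <- sum(y == "normal" & predicted == "normal", na.rm = TRUE)
  m <- metrics(tp, fp, fn, tn)
  m_normal <- metrics(tp = tn, fp = fn, fn = fp, tn = tp)

  structure(
    list(
      per_fold = data.frame(subject_id = subject_ids[used], truth = y[used],
                            predicted = predicted[used],
                            stringsAsFactors = FALSE),
      confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
      accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      precision_normal = m_normal$precision, recall_normal = m_normal$recall,
      skipped_folds = skipped, method = method, combo = combo, n = sum(used)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s%s: n = %d folds\n", x$method,
              if (is.na(x$combo)) "" else paste0(" on ", x$combo), x$n))
  cat(sprintf("  confusion (palsy positive): TP %d  FP %d  FN %d  TN %d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tn"]))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f\n",
              x$accuracy, x$precision, x$recall))
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}
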