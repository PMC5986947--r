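# Stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt round-robin into k folds, so every fold holds
# approximately the same number of observations from each class.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (any(table(y) < k))
    stop(sprintf("every class needs >= %d samples for %d-fold CV", k, k))
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    i <- sample(which(y == cl))
    folds[i] <- rep_len(seq_len(k), length(i))
  }
  folds
}

cv_result <- function(per_unit, config) {
  per_unit <- as.data.frame(per_unit)
  mean_ <- colMeans(per_unit, na.rm = TRUE)
  n <- colSums(!is.na(per_unit))
  se <- apply(per_unit, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- list(per_unit = per_unit, mean = mean_, se = se,
              n_undefined = colSums(is.na(per_unit)), config = config)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d unit%s\n", nrow(x$per_unit),
              if (nrow(x$per_unit) == 1) "" else "s"))
  m <- rbind(mean = x$mean, se = x$se)
  print(round(m, 4))
  if (any(x$n_undefined > 0))
    cat("undefined (excluded from means):",
        paste(sprintf("%s:%d", names(x$n_undefined),
                      x$n_undefined)[x$n_undefined > 0], collapse = ", "),
        "\n")
  invisible(x)
}

default_positive <- function(y) {
  lv <- levels(factor(y))
  if ("nif" %in% lv) "nif" else lv[1]
}

#' Stratified k-fold cross-validation of a binary SVM
#'
#' Splits the data at random into `k` stratified folds (each containing
#' approximately the same number of observations from both classes), trains
#' on k-1 folds and tests on the held-out fold so that every sample is
#' tested exactly once, and reports the per-fold performance metrics with
#' their mean and standard error.
#'
#' @param x Feature matrix.
#' @param y Binary class labels.
#' @param k Number of folds (default 5).
#' @param kernel A [kernel_spec()] or kernel name.
#' @param seed Integer seed governing fold assignment and fitting.
#' @param positive Label treated as positive (default `"nif"` when
#'   present, otherwise the first level).
#' @return A `cv_result` with per-fold metric rows, their mean, and
#'   standard errors.
#' @export
kfold_cv <- function(x, y, k = 5L, kernel = kernel_spec("radial"),
                     seed = 1L, positive = default_positive(y)) {
  x <- as.matrix(x)
  y <- factor(y)
  folds <- stratified_folds(y, k, seed)
  per_fold <- matrix(NA_real_, nrow = k, ncol = 5,
                     dimnames = list(NULL, c("Sn", "Sp", "Ac", "Pre", "MCC")))
  for (f in seq_len(k)) {
    te <- folds == f
    m <- train_svm(x[!te, , drop = FALSE], y[!te], kernel = kernel,
                   seed = seed + f)
    p <- predict_scores(m, x[te, , drop = FALSE])
    per_fold[f, ] <- metrics_from_counts(
      confusion_counts(as.character(y[te]), p$label, positive))
  }
  cv_result(per_fold, list(k = k, seed = seed, positive = positive,
                           kernel = as_kernel_spec(kernel)$name))
}

#' Jackknife (leave-one-out) validation of a multi-class SVM
#'
#' Fits n models, each trained on all observations except one and tested
#' on the left-out observation, and aggregates the n predictions into a
#' confusion matrix (rows = true class, columns = predicted class) with
#' one-vs-rest performance metrics per class.
#'
#' @param x Feature matrix.
#' @param y Class labels; every class needs at least 2 members (a
#'   singleton class would be untrainable when its member is left out).
#' @param kernel A [kernel_spec()] or kernel name.
#' @param seed Integer seed for fitting.
#' @return A `multiclass_report`: list with `confusion` (class x class
#'   matrix), `per_class` (class x metric matrix of one-vs-rest `Sn`,
#'   `Sp`, `Ac`, `Pre`, `MCC`), and `n`.
#' @export
jackknife_cv <- function(x, y, kernel = kernel_spec("radial"), seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (length(y) < 3L) stop("need at least 3 observations for jackknife")
  small <- names(which(table(y) < 2L))
  if (length(small))
    stop("classes with a single member cannot be jackknifed: ",
         paste(small, collapse = ", "))
  lv <- levels(y)
  pred <- character(length(y))
  for (i in seq_along(y)) {
    m <- train_svm(x[-i, , drop = FALSE], y[-i], kernel = kernel,
                   seed = seed)
    pred[i] <- predict_scores(m, x[i, , drop = FALSE])$label
  }
  confusion <- table(true = factor(as.character(y), levels = lv),
                     predicted = factor(pred, levels = lv))
  confusion <- unclass(confusion)
  per_class <- t(vapply(lv, function(cl) {
    metrics_from_counts(confusion_counts(as.character(y), pred, cl))
  }, numeric(5)))
  colnames(per_class) <- c("Sn", "Sp", "Ac", "Pre", "MCC")
  out <- list(confusion = confusion, per_class = per_class, n = length(y),
              config = list(kernel = as_kernel_spec(kernel)$name,
                            seed = seed))
  class(out) <- "multiclass_report"
  out
}

#' @export
print.multiclass_report <- function(x, ...) {
  cat(sprintf("jackknife validation of %d observations\nconfusion matrix (rows = true):\n",
              x$n))
  print(x$confusion)
  cat("per-class one-vs-rest metrics:\n")
  print(round(x$per_class, 4))
  invisible(x)
}

#' Balanced-resampling cross-validation for imbalanced binary data
#'
#' When negatives vastly outnumber positives, a single random negative
#' draw is not representative. This harness repeats, for `M` sample sets:
#' draw as many negatives as there are positives (uniformly, without
#' replacement within a draw, independently across draws), run stratified
#' k-fold cross-validation on the balanced set, and record the mean
#' metrics. The grand mean over the `M` sets and its standard error
#' estimate the classifier's balanced performance.
#'
#' @param pos Feature matrix of positive-class samples.
#' @param neg Feature matrix of negative-class samples; must have at least
#'   as many rows as `pos`.
#' @param M Number of balanced sample sets (default 100).
#' @param k Folds within each sample set (default 5).
#' @param kernel A [kernel_spec()] or kernel name.
#' @param seed Integer seed; draw m uses `seed + m`.
#' @param positive,negative Labels given to the two classes.
#' @return A `cv_result` whose units are the per-sample-set mean metrics.
#' @export
balanced_resampling_cv <- function(pos, neg, M = 100L, k = 5L,
                                   kernel = kernel_spec("radial"),
                                   seed = 1L, positive = "nif",
                                   negative = "non-nif") {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (ncol(pos) != ncol(neg))
    stop("positive and negative matrices must have the same columns")
  if (nrow(neg) < nrow(pos))
    stop(sprintf("need at least as many negatives (%d) as positives (%d)",
                 nrow(neg), nrow(pos)))
  n_pos <- nrow(pos)
  per_set <- matrix(NA_real_, nrow = M, ncol = 5,
                    dimnames = list(NULL, c("Sn", "Sp", "Ac", "Pre", "MCC")))
  for (m in seq_len(M)) {
    set.seed(seed + m)
    draw <- sample(nrow(neg), n_pos)
    x <- rbind(pos, neg[draw, , drop = FALSE])
    y <- factor(rep(c(positive, negative), each = n_pos))
    res <- kfold_cv(x, y, k = k, kernel = kernel, seed = seed + m,
                    positive = positive)
    per_set[m, ] <- res$mean
  }
  cv_result(per_set, list(M = M, k = k, seed = seed, positive = positive,
                          kernel = as_kernel_spec(kernel)$name))
}
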