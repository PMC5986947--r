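#' Specify an SVM kernel
#'
#' Captures the kernel family and its parameters at the defaults of the
#' underlying SVM implementation (e1071): `cost = 1`,
#' `gamma = 1/#features` (resolved at fit time when `NULL`), `degree = 3`
#' for the polynomial kernel and `coef0 = 0` for polynomial and sigmoid.
#'
#' @param name One of `"radial"`, `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param cost Positive regularization cost.
#' @param gamma Positive kernel width, or `NULL` for 1/#features.
#' @param degree Polynomial degree (>= 1).
#' @param coef0 Offset for polynomial/sigmoid kernels.
#' @return A `kernel_spec` object.
#' @export
#' @examples
#' kernel_spec("radial")
kernel_spec <- function(name = c("radial", "linear", "polynomial", "sigmoid"),
                        cost = 1, gamma = NULL, degree = 3L, coef0 = 0) {
  name <- match.arg(name)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0, degree >= 1)
  out <- list(name = name, cost = cost, gamma = gamma,
              degree = as.integer(degree), coef0 = coef0)
  class(out) <- "kernel_spec"
  out
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("SVM kernel: %s (cost = %g, gamma = %s, degree = %d, coef0 = %g)\n",
              x$name, x$cost,
              if (is.null(x$gamma)) "1/#features" else format(x$gamma),
              x$degree, x$coef0))
  invisible(x)
}

as_kernel_spec <- function(kernel) {
  if (inherits(kernel, "kernel_spec")) kernel
  else kernel_spec(kernel)
}

# Column standardization learned on training data; constant columns get
# scale 1 so they pass through unchanged.
learn_scaling <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaling <- function(x, scaling) {
  scale(x, center = scaling$center, scale = scaling$scale)[, , drop = FALSE]
}

#' Train an SVM on a feature matrix
#'
#' Fits a support vector machine (binary or multi-class, one-vs-one
#' decomposition) with Platt-style probability calibration. Feature
#' columns are standardized with center/scale learned from the training
#' matrix only; the same scaling is applied to queries at prediction time.
#' All stochastic steps (the calibration folds) are governed by `seed`, so
#' refitting with identical inputs reproduces identical predictions.
#'
#' @param x A `feature_matrix` (or plain numeric matrix) of training rows.
#' @param y Class labels, one per row; at least two classes with at least
#'   two members each.
#' @param kernel A [kernel_spec()] or kernel name.
#' @param seed Integer seed for the stochastic parts of fitting.
#' @return A `nif_svm` model.
#' @importFrom e1071 svm
#' @export
train_svm <- function(x, y, kernel = kernel_spec("radial"), seed = 1L) {
  kernel <- as_kernel_spec(kernel)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("feature matrix contains non-finite values")
  y <- factor(y)
  if (nrow(x) != length(y))
    stop(sprintf("row count (%d) does not match label count (%d)",
                 nrow(x), length(y)))
  if (nlevels(y) < 2L) stop("need at least 2 classes, got 1")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  scaling <- learn_scaling(x)
  xs <- apply_scaling(x, scaling)
  gamma <- kernel$gamma %||% (1 / ncol(x))
  set.seed(seed)
  fit <- e1071::svm(xs, y, kernel = kernel$name, cost = kernel$cost,
                    gamma = gamma, degree = kernel$degree,
                    coef0 = kernel$coef0, probability = TRUE, scale = FALSE)
  out <- list(fit = fit, kernel = kernel, gamma = gamma,
              class_labels = levels(y), scaling = scaling,
              n_features = ncol(x),
              scheme = attr(x, "scheme"), params = attr(x, "params"),
              stage = if (nlevels(y) == 2L) "binary" else "multiclass",
              seed = seed, version = "1")
  class(out) <- "nif_svm"
  out
}

#' @export
print.nif_svm <- function(x, ...) {
  cat(sprintf("nif_svm: %s SVM, %s kernel, %d features, classes: %s\n",
              x$stage, x$kernel$name, x$n_features,
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

#' Predict class probabilities with a trained SVM
#'
#' Returns one row per query with the calibrated probability of each class,
#' the argmax label (ties broken by class-label order) and the maximum
#' probability.
#'
#' @param model A `nif_svm` from [train_svm()].
#' @param x Feature matrix with the column count the model was trained on.
#' @return A data frame with columns `id`, one `prob.<class>` column per
#'   class, `label`, and `prob_max`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "nif_svm"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) {
    out <- data.frame(id = character(), label = character(),
                      prob_max = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  if (ncol(x) != model$n_features)
    stop(sprintf("feature dimension mismatch: expected %d, got %d",
                 model$n_features, ncol(x)))
  xs <- apply_scaling(x, model$scaling)
  pred <- stats::predict(model$fit, xs, probability = TRUE)
  probs <- attr(pred, "probabilities")[, model$class_labels, drop = FALSE]
  amax <- apply(probs, 1, which.max)  # first max: class-label order
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  out <- data.frame(id = ids, probs,
                    label = model$class_labels[amax],
                    prob_max = probs[cbind(seq_len(nrow(probs)), amax)],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(model$class_labels) + 1L] <-
    paste0("prob.", model$class_labels)
  rownames(out) <- NULL
  out
}

#' Select the best-fitting kernel on a class-balanced subset
#'
#' Draws a seeded subset of `subset_per_class` samples from each class
#' (the whole class, with a warning, when it is smaller), runs stratified
#' five-fold cross-validation for each of the four basic kernels at default
#' parameters, and returns the kernel with the highest mean accuracy. Ties
#' are broken in the fixed order radial > polynomial > sigmoid > linear.
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param subset_per_class Samples drawn per class (default 100).
#' @param k Folds for the per-kernel cross-validation.
#' @param seed Integer seed for subsetting and fold assignment.
#' @return A [kernel_spec()] for the winning kernel, with the per-kernel
#'   mean accuracies in attribute `accuracy`.
#' @export
select_kernel <- function(x, y, subset_per_class = 100L, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes for kernel selection")
  set.seed(seed)
  take <- unlist(lapply(levels(y), function(cl) {
    i <- which(y == cl)
    if (length(i) < subset_per_class) {
      warning(sprintf("class '%s' has only %d samples (< %d); using all",
                      cl, length(i), subset_per_class))
      i
    } else sample(i, subset_per_class)
  }))
  xs <- x[take, , drop = FALSE]
  ys <- droplevels(y[take])
  order <- c("radial", "polynomial", "sigmoid", "linear")
  acc <- vapply(order, function(kern) {
    folds <- stratified_folds(ys, k, seed = seed + 1L)
    correct <- 0L
    for (f in seq_len(k)) {
      te <- folds == f
      m <- train_svm(xs[!te, , drop = FALSE], ys[!te],
                     kernel = kernel_spec(kern), seed = seed + f)
      p <- predict_scores(m, xs[te, , drop = FALSE])
      correct <- correct + sum(p$label == as.character(ys[te]))
    }
    correct / length(ys)
  }, numeric(1))
  best <- order[which.max(acc)]  # which.max keeps the tie-break order
  out <- kernel_spec(best)
  attr(out, "accuracy") <- acc
  out
}

#' Save and load trained models
#'
#' Model persistence keeps the kernel specification, feature scaling,
#' scheme and parameters, label order and fitted state in one archive.
#' A version tag is checked on load.
#'
#' @param model A `nif_svm` or `nif_model` object.
#' @param path Archive file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nif_svm") || inherits(model, "nif_model"))
  saveRDS(list(format_version = "nifclass-model-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format_version, "nifclass-model-1"))
    stop("not a nifclass model archive (missing or unknown version tag)")
  obj$model
}
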