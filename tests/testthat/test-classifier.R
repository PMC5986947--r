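# Shared small fixtures: separable and null two-class data under AAC
# (20 features keeps the SVM fits fast).
sep_data <- local({
  d <- two_class_dataset(50, delta = 0.3, seed = 21)
  list(x = encode_dataset(d$sequences, "aac"), y = d$labels)
})
null_data <- local({
  d <- two_class_dataset(50, delta = 0, seed = 22)
  list(x = encode_dataset(d$sequences, "aac"), y = d$labels)
})

test_that("kernel_spec applies the reference defaults and validates names", {
  k <- kernel_spec("radial")
  expect_equal(k$cost, 1)
  expect_null(k$gamma)
  expect_equal(k$degree, 3L)
  expect_equal(k$coef0, 0)
  expect_error(kernel_spec("spline"))
})

test_that("training on separable classes reaches perfect training accuracy", {
  m <- train_svm(sep_data$x, sep_data$y, kernel_spec("radial"), seed = 1)
  p <- predict_scores(m, sep_data$x)
  expect_equal(mean(p$label == sep_data$y), 1)
})

test_that("train_svm rejects degenerate inputs", {
  expect_error(train_svm(sep_data$x, rep("A", nrow(sep_data$x))),
               "at least 2 classes")
  expect_error(train_svm(sep_data$x, sep_data$y[-1]), "does not match")
  x <- sep_data$x; x[1, 1] <- NA
  expect_error(train_svm(x, sep_data$y), "non-finite")
})

test_that("fits are reproducible under a seed", {
  probe <- encode_dataset(two_class_dataset(10, 0.3, seed = 33)$sequences,
                          "aac")
  m1 <- train_svm(sep_data$x, sep_data$y, seed = 5)
  m2 <- train_svm(sep_data$x, sep_data$y, seed = 5)
  expect_identical(predict_scores(m1, probe), predict_scores(m2, probe))
})

test_that("predictions expose calibrated probabilities and argmax", {
  m <- train_svm(sep_data$x, sep_data$y, seed = 1)
  p <- predict_scores(m, sep_data$x)
  probs <- as.matrix(p[, c("prob.A", "prob.B")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-6)
  expect_equal(p$label,
               c("A", "B")[apply(probs, 1, which.max)])
  expect_equal(nrow(predict_scores(m, sep_data$x[0, , drop = FALSE])), 0)
  expect_error(predict_scores(m, sep_data$x[, 1:10]), "expected 20, got 10")
})

test_that("internal standardization absorbs column rescaling", {
  probe <- encode_dataset(two_class_dataset(10, 0.3, seed = 34)$sequences,
                          "aac")
  m1 <- train_svm(sep_data$x, sep_data$y, seed = 2)
  x10 <- sep_data$x; x10[, 3] <- x10[, 3] * 10
  p10 <- probe; p10[, 3] <- p10[, 3] * 10
  m2 <- train_svm(x10, sep_data$y, seed = 2)
  expect_equal(predict_scores(m1, probe)$prob_max,
               predict_scores(m2, p10)$prob_max, tolerance = 1e-9)
})

test_that("probability calibration is confident only when there is signal", {
  probe_null <- encode_dataset(
    two_class_dataset(30, 0, seed = 40)$sequences, "aac")
  probe_sep <- encode_dataset(
    two_class_dataset(30, 0.3, seed = 41)$sequences, "aac")
  m_null <- train_svm(null_data$x, null_data$y, seed = 3)
  m_sep <- train_svm(sep_data$x, sep_data$y, seed = 3)
  expect_lte(mean(predict_scores(m_null, probe_null)$prob_max), 0.75)
  expect_gte(mean(predict_scores(m_sep, probe_sep)$prob_max), 0.9)
})

test_that("a multiclass model restricted to two classes agrees with the binary model", {
  d <- multiclass_dataset(20, n_classes = 3, signal = 0.6, seed = 44)
  x <- encode_dataset(d$sequences, "ctd")
  m_all <- train_svm(x, d$labels, seed = 6)
  two <- d$labels %in% unique(d$labels)[1:2]
  m_bin <- train_svm(x[two, , drop = FALSE], d$labels[two], seed = 6)
  probe_d <- multiclass_dataset(10, n_classes = 3, signal = 0.6, seed = 45)
  keep <- probe_d$labels %in% unique(d$labels)[1:2]
  probe <- encode_dataset(probe_d$sequences, "ctd")[keep, , drop = FALSE]
  agree <- mean(predict_scores(m_all, probe)$label ==
                  predict_scores(m_bin, probe)$label)
  expect_gte(agree, 0.9)
})

test_that("select_kernel picks radial on annulus-style data, stably across seeds", {
  # class A sits at a moderate composition shift; class B mixes no shift
  # with a strong shift, surrounding A along the shift axis so only a
  # radial boundary separates them
  shifted_class <- function(n, delta, seed, prefix) {
    d <- two_class_dataset(n, delta, seed = seed)
    s <- d$sequences[d$labels == "B", ]
    s$id <- paste0(prefix, "_", seq_len(nrow(s)))
    s
  }
  a <- shifted_class(60, 0.25, 1, "mid")
  b <- rbind(shifted_class(30, 0, 2, "inner"),
             shifted_class(30, 0.5, 3, "outer"))
  seqs <- rbind(a, b)
  class(seqs) <- c("protein_set", "data.frame")
  x <- encode_dataset(seqs, "aac")
  y <- rep(c("A", "B"), each = 60)
  for (s in 1:2) {
    k <- select_kernel(x, y, subset_per_class = 60, seed = s)
    expect_s3_class(k, "kernel_spec")
    acc <- attr(k, "accuracy")
    expect_named(acc, c("radial", "polynomial", "sigmoid", "linear"))
    expect_equal(k$name, "radial")
    expect_equal(k$name, names(acc)[which.max(acc)])
  }
  expect_error(select_kernel(x, rep("A", nrow(x))), "2 classes")
})

test_that("select_kernel ties break toward radial and small classes warn", {
  # trivially separable homopolymer-like classes: several kernels reach
  # identical (perfect) accuracy and the fixed preference order decides
  pa <- random_sequences(6, c(60, 60),
                         composition_profile(c(rep(1, 2), rep(0, 18))),
                         seed = 5, prefix = "pa")
  pb <- random_sequences(6, c(60, 60),
                         composition_profile(c(rep(0, 8), 1, 1, rep(0, 10))),
                         seed = 6, prefix = "pb")
  seqs <- rbind(pa, pb)
  class(seqs) <- c("protein_set", "data.frame")
  x <- encode_dataset(seqs, "aac")
  y <- rep(c("a", "b"), each = 6)
  k <- select_kernel(x, y, subset_per_class = 6, seed = 1)
  acc <- attr(k, "accuracy")
  expect_gte(sum(acc == max(acc)), 2)  # a genuine tie is being broken
  expect_equal(k$name, "radial")
  w <- capture_warnings(select_kernel(x, y, subset_per_class = 1000,
                                      seed = 1))
  expect_length(w, 2)  # one warning per undersized class
  expect_match(w, "using all", all = TRUE)
})

test_that("model persistence round-trips and checks its version tag", {
  m <- train_svm(sep_data$x, sep_data$y, seed = 9)
  probe <- encode_dataset(two_class_dataset(5, 0.3, seed = 46)$sequences,
                          "aac")
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_scores(m, probe), predict_scores(m2, probe))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), bad)
  expect_error(load_model(bad), "version tag")
})
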