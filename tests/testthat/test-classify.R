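test_that("z-score normalization fits on train only and inverts exactly", {
  set.seed(901)
  x <- matrix(rnorm(200), 20, 10)
  p <- normalize_fit(x)
  z <- normalize_apply(p, x)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_equal(apply(z, 2, function(v) sqrt(mean((v - mean(v))^2))),
               rep(1, 10), tolerance = 1e-9)
  back <- normalize_invert(p, z)
  expect_equal(back, x, tolerance = 1e-10)

  # constant features map to zero, with a warning
  xc <- cbind(x, 42)
  expect_warning(pc <- normalize_fit(xc), "zero-variance")
  zc <- normalize_apply(pc, xc)
  expect_true(all(zc[, 11] == 0))

  # parameters are a property of the training rows alone
  xtest <- matrix(rnorm(50, mean = 100), 5, 10)  # wild outliers on test side
  expect_equal(normalize_fit(x)$center, p$center)
  z2 <- normalize_apply(p, xtest)
  expect_equal(normalize_invert(p, z2), xtest, tolerance = 1e-9)
})

test_that("svm separates blobs and learns xor", {
  set.seed(902)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 5), ncol = 2))
  y <- rep(c("NC", "LF"), each = 50)
  p <- normalize_fit(x)
  m <- svm_train(normalize_apply(p, x), y, classifier_config(C = 10))
  expect_identical(mean(predict(m, normalize_apply(p, x)) == y), 1)

  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  xor_y <- c("NC", "LF", "LF", "NC")
  mx <- svm_train(xor_x, xor_y,
                  classifier_config(C = 100, gamma_rule = "fixed",
                                    gamma_value = 2))
  expect_identical(predict(mx, xor_x), xor_y)

  expect_error(svm_train(x, rep("NC", 100)), "at least 2 classes")
})

test_that("cross-validation is stratified, deterministic and leak free", {
  set.seed(903)
  n_per <- 60
  mu <- rbind(NC = c(0, 0), LF = c(4, 0), TR = c(0, 4), SE = c(4, 4))
  feats <- do.call(rbind, lapply(rownames(mu), function(cl) {
    data.frame(trial_id = paste0(cl, 1:n_per), subject_id = "S1",
               group = "healthy", window_start = 1, label = cl,
               f1 = rnorm(n_per, mu[cl, 1], 0.3),
               f2 = rnorm(n_per, mu[cl, 2], 0.3))
  }))
  cfg <- classifier_config(seed = 7)
  rep1 <- crossvalidate(feats, cfg)
  # separable blobs: perfect accuracy and diagonal confusion
  expect_identical(rep1$accuracy, 1)
  expect_identical(sum(rep1$confusion) - sum(diag(rep1$confusion)), 0L)

  # determinism under identical seed/config; seeds move the fold assignment
  rep2 <- crossvalidate(feats, cfg)
  expect_identical(rep1, rep2)
  expect_false(identical(
    nirscomp:::make_folds(feats$label, seq_len(nrow(feats)), 10, 7),
    nirscomp:::make_folds(feats$label, seq_len(nrow(feats)), 10, 8)))

  # stratified fold sizes differ by at most 1 per class
  fold <- nirscomp:::make_folds(feats$label, seq_len(nrow(feats)), 10, 7)
  per_class <- table(feats$label, fold)
  expect_true(all(apply(per_class, 1, function(r) diff(range(r)) <= 1)))

  # outlier injected into one fold's test rows leaves the training-side
  # normalization of other rows untouched (no leakage through scaling)
  test_rows <- which(fold == 1)
  train_x <- as.matrix(feats[-test_rows, c("f1", "f2")])
  p_before <- normalize_fit(train_x)
  feats_outlier <- feats
  feats_outlier[test_rows, c("f1", "f2")] <- 1e6
  p_after <- normalize_fit(as.matrix(feats_outlier[-test_rows, c("f1", "f2")]))
  expect_identical(p_before$center, p_after$center)
  expect_identical(p_before$scale, p_after$scale)
})

test_that("chance-level accuracy on permuted labels", {
  set.seed(904)
  n <- 400
  feats <- data.frame(trial_id = as.character(1:n), subject_id = "S1",
                      group = "healthy", window_start = 1,
                      label = sample(rep(c("NC", "LF", "TR", "SE"), n / 4)),
                      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  accs <- vapply(1:3, function(i) {
    suppressWarnings(crossvalidate(feats, classifier_config(seed = i))$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.06)
})

test_that("confusion-matrix metrics match hand computations", {
  cm <- diag(c(10, 10, 10, 10))
  dimnames(cm) <- list(NIRS_CLASSES, NIRS_CLASSES)
  m <- evaluate_metrics(cm)
  expect_identical(m$accuracy, 1)
  expect_true(all(m$per_class$f1 == 1))
  expect_identical(m$macro_f1, 1)

  cm2 <- matrix(0L, 4, 4, dimnames = list(NIRS_CLASSES, NIRS_CLASSES))
  cm2[1:2, 1:2] <- c(9L, 1L, 1L, 9L)
  mw <- suppressWarnings(evaluate_metrics(cm2))
  expect_equal(mw$per_class$precision[1], 0.9)
  expect_equal(mw$per_class$recall[1], 0.9)
  expect_equal(mw$per_class$f1[1], 0.9)
  expect_equal(mw$accuracy, 0.9)

  expect_warning(z <- evaluate_metrics(matrix(0L, 4, 4)), "zero denominator|empty")
  expect_true(all(unlist(z$per_class[, -1]) == 0))
  expect_identical(z$accuracy, 0)
  expect_error(evaluate_metrics(matrix(-1, 4, 4)), "non-negative")

  # F1 is the harmonic mean of precision and recall
  cm3 <- matrix(c(8L, 2L, 1L, 9L), 2, 2)
  m3 <- evaluate_metrics(cm3)
  with(m3$per_class, expect_equal(f1, 2 * precision * recall / (precision + recall)))
})

test_that("fold counts exceeding rows are rejected", {
  feats <- data.frame(trial_id = as.character(1:8), subject_id = "S1",
                      group = "healthy", window_start = 1,
                      label = rep(c("NC", "LF"), 4), f1 = rnorm(8))
  expect_error(crossvalidate(feats, classifier_config(folds = 9)),
               "more folds than rows")
})
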