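#' Classifier configuration
#'
#' Four-class soft-margin SVM with Gaussian radial-basis kernel, penalty
#' `C = 0.3`, one-vs-one multiclass voting (libsvm's native scheme), z-score
#' normalization fitted per training split, and stratified ten-fold
#' cross-validation.
#'
#' @param C soft-margin penalty.
#' @param gamma_rule RBF width rule: `"inverse_nfeat_var"`
#'   (\eqn{1/(p \cdot \overline{var})}, scale-free default),
#'   `"inverse_nfeat"` (\eqn{1/p}), or `"fixed"`.
#' @param gamma_value gamma when `gamma_rule = "fixed"`.
#' @param folds number of cross-validation folds.
#' @param split_unit unit of the random partition: `"window"` mirrors a
#'   random sample-level split; `"trial"` and `"subject"` avoid leaking
#'   temporally adjacent windows across folds.
#' @param normalization `"zscore"` or `"minmax"`.
#' @param seed integer seed for fold assignment.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(C = 0.3,
                              gamma_rule = c("inverse_nfeat_var",
                                             "inverse_nfeat", "fixed"),
                              gamma_value = NULL,
                              folds = 10,
                              split_unit = c("window", "trial", "subject"),
                              normalization = c("zscore", "minmax"),
                              seed = 1L) {
  gamma_rule <- match.arg(gamma_rule)
  split_unit <- match.arg(split_unit)
  normalization <- match.arg(normalization)
  stopifnot(C > 0, folds >= 2)
  if (gamma_rule == "fixed" && is.null(gamma_value)) {
    stopf("classifier_config: gamma_value required when gamma_rule = 'fixed'")
  }
  structure(list(C = C, kernel = "rbf", gamma_rule = gamma_rule,
                 gamma_value = gamma_value, multiclass = "one_vs_one",
                 folds = folds, split_unit = split_unit,
                 normalization = normalization, seed = seed),
            class = "classifier_config")
}

#' Fit normalization parameters on training rows
#'
#' Z-score (default) or min-max parameters per feature, fitted on the
#' training split only so no information leaks from test rows through the
#' scaling. Zero-variance (or zero-range) features are mapped to 0 with a
#' warning.
#'
#' @param x numeric matrix or data frame of training feature rows.
#' @param method `"zscore"` or `"minmax"`.
#' @return a `normalization_params` list.
#' @export
normalize_fit <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("normalize_fit: no training rows")
  if (method == "zscore") {
    center <- colMeans(x)
    scale_ <- apply(x, 2, pop_sd)
  } else {
    center <- apply(x, 2, min)
    scale_ <- apply(x, 2, max) - center
  }
  degenerate <- scale_ == 0
  if (any(degenerate)) {
    warning(sprintf("normalize_fit: %d zero-variance feature(s) mapped to 0",
                    sum(degenerate)), call. = FALSE)
    scale_[degenerate] <- 1
    center[degenerate] <- if (method == "zscore") center[degenerate]
                          else center[degenerate]
  }
  structure(list(method = method, center = center, scale = scale_,
                 degenerate = degenerate),
            class = "normalization_params")
}

#' Apply fitted normalization parameters
#'
#' @param params a `normalization_params` from [normalize_fit()].
#' @param x rows to transform (train or test).
#' @return normalized numeric matrix.
#' @export
normalize_apply <- function(params, x) {
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, params$center), 2, params$scale, "/")
  out[, params$degenerate] <- 0
  out
}

#' Invert fitted normalization
#' @inheritParams normalize_apply
#' @return matrix on the original scale (degenerate features return their
#'   fitted constant).
#' @export
normalize_invert <- function(params, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$scale, "*"), 2, params$center, "+")
}

resolve_gamma <- function(config, x) {
  switch(config$gamma_rule,
    inverse_nfeat_var = {
      v <- mean(apply(x, 2, var))
      if (!is.finite(v) || v == 0) v <- 1
      1 / (ncol(x) * v)
    },
    inverse_nfeat = 1 / ncol(x),
    fixed = config$gamma_value
  )
}

#' Train the one-vs-one RBF SVM
#'
#' Soft-margin SVM ensemble (one binary classifier per class pair, pairwise
#' voting) with Gaussian kernel and penalty `C` from the configuration,
#' through libsvm. Class order is fixed at NC < LF < TR < SE so voting ties
#' resolve deterministically to the lowest class index. Rows are expected to
#' be normalized already (see [normalize_fit()]); libsvm's internal scaling is
#' disabled.
#'
#' @param x numeric feature matrix.
#' @param y class labels (character or factor).
#' @param config a [classifier_config()].
#' @return fitted model of class `svm_model`.
#' @export
svm_train <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("svm_train: features contain non-finite values")
  y <- factor(as.character(y), levels = intersect(NIRS_CLASSES, unique(as.character(y))))
  if (nlevels(y) < 2) stopf("svm_train: need at least 2 classes")
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = config$C, gamma = resolve_gamma(config, x),
                    scale = FALSE)
  structure(list(fit = fit, levels = levels(y), config = config),
            class = "svm_model")
}

#' Predict classes with a trained model
#' @param object an `svm_model`.
#' @param newdata numeric feature matrix (normalized with the same
#'   parameters as the training rows).
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

# stratified fold assignment; `units` groups rows that must stay together
make_folds <- function(labels, units, folds, seed) {
  set.seed(derive_seed(seed, 3L))
  uu <- unique(units)
  unit_label <- labels[match(uu, units)]
  fold_of_unit <- integer(length(uu))
  for (cl in unique(unit_label)) {
    idx <- which(unit_label == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of_unit[idx] <- rep_len(sample.int(folds), length(idx))
  }
  fold_of_unit[match(units, uu)]
}

#' Stratified k-fold cross-validated evaluation
#'
#' Rows are partitioned into `folds` parts, stratified by class at the
#' configured split unit (window, trial or subject). For each fold the
#' normalization and SVM are fitted on the remaining parts and evaluated on
#' the held-out part; per-fold accuracies, the pooled confusion matrix and
#' per-class metrics are reported. Deterministic under the configuration
#' seed.
#'
#' @param features feature matrix from [extract_features()] (provenance
#'   columns plus features), or a plain data frame with a `label` column.
#' @param config a [classifier_config()].
#' @return an `evaluation_report`: `fold_accuracy`, `accuracy` (mean of fold
#'   accuracies), `pooled_accuracy`, `confusion` (rows = true), `per_class`
#'   precision/recall/F1, `macro_f1`, and the configuration echo.
#' @export
crossvalidate <- function(features, config = classifier_config()) {
  labels <- features$label
  x <- as.matrix(features[, feature_columns(features), drop = FALSE])
  if (config$folds > nrow(x)) stopf("crossvalidate: more folds than rows")
  units <- switch(config$split_unit,
    window = seq_len(nrow(x)),
    trial = features$trial_id,
    subject = features$subject_id
  )
  fold <- make_folds(labels, units, config$folds, config$seed)

  classes <- intersect(NIRS_CLASSES, unique(labels))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) { fold_acc[f] <- NA_real_; next }
    params <- suppressWarnings(normalize_fit(x[tr, , drop = FALSE],
                                             config$normalization))
    model <- svm_train(normalize_apply(params, x[tr, , drop = FALSE]),
                       labels[tr], config)
    pred <- predict(model, normalize_apply(params, x[te, , drop = FALSE]))
    fold_acc[f] <- mean(pred == labels[te])
    tab <- table(factor(labels[te], levels = classes),
                 factor(pred, levels = classes))
    confusion <- confusion + as.matrix(tab)
  }
  metrics <- evaluate_metrics(confusion)
  structure(
    list(fold_accuracy = fold_acc,
         accuracy = mean(fold_acc, na.rm = TRUE),
         pooled_accuracy = metrics$accuracy,
         confusion = confusion,
         per_class = metrics$per_class,
         macro_f1 = metrics$macro_f1,
         config = config),
    class = "evaluation_report"
  )
}

#' Metrics from a confusion matrix
#'
#' Per-class precision (column-wise), recall (row-wise, rows = true class),
#' and F1 (harmonic mean), plus overall accuracy and macro-F1. Zero
#' denominators yield 0 with a warning.
#'
#' @param confusion square non-negative integer matrix, rows = true classes.
#' @return list with `per_class` (data frame), `accuracy`, `macro_f1`.
#' @export
evaluate_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stopf("confusion matrix must be square")
  if (any(confusion < 0)) stopf("confusion matrix entries must be non-negative")
  total <- sum(confusion)
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sprintf("evaluate_metrics: zero denominator in %s set to 0", what),
              call. = FALSE)
    }
    out <- ifelse(bad, 0, num / ifelse(bad, 1, den))
    out
  }
  d <- diag(confusion)
  precision <- safe_div(d, colSums(confusion), "precision")
  recall <- safe_div(d, rowSums(confusion), "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  accuracy <- if (total == 0) {
    warning("evaluate_metrics: empty confusion matrix", call. = FALSE)
    0
  } else sum(d) / total
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(confusion)))
  list(per_class = data.frame(class = classes, precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1)),
       accuracy = accuracy,
       macro_f1 = mean(f1))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("4-class SVM evaluation (%d-fold CV, split by %s)\n",
              x$config$folds, x$config$split_unit))
  cat(sprintf("  accuracy (mean of folds): %.4f\n", x$accuracy))
  cat(sprintf("  accuracy (pooled):        %.4f\n", x$pooled_accuracy))
  cat(sprintf("  macro-F1:                 %.4f\n", x$macro_f1))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
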