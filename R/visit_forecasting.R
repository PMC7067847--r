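# Visit forecasting: classify change vectors as pre-visit (true) vs
# pre-random (null). Standardization + PCA fitted on training folds only, a
# linear (probability-averaging) ensemble of random forest, SVM, gradient
# boosting and logistic regression, patient-exclusive k-fold CV, and a
# ridge-penalized logistic control model.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, ties counted half.
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1 labels (1 = true event).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  lx_assert(length(scores) == length(labels), "lexicross_shape_error",
            "scores and labels must have equal length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  lx_assert(n1 > 0 && n0 > 0, "lexicross_degenerate",
            "AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold, tie-grouped so the
#' trapezoidal area equals the rank-based AUC; starts at (0,0), ends at
#' (1,1).
#'
#' @inheritParams compute_auc
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  lx_assert(n1 > 0 && n0 > 0, "lexicross_degenerate",
            "ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, cumsum(l == 0L)[last_of_tie] / n0),
             tpr = c(0, cumsum(l == 1L)[last_of_tie] / n1))
}

#' F1 score at a probability threshold
#'
#' Harmonic mean of precision and recall, predictions being
#' `scores >= threshold`; 0 when no positive predictions or positives exist.
#'
#' @inheritParams compute_auc
#' @param threshold Probability cutoff, default 0.5.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  denom <- 2 * tp + sum(pred == 1L & labels == 0L) +
    sum(pred == 0L & labels == 1L)
  if (denom == 0) return(0)
  2 * tp / denom
}

#' Build the classification matrix from cohort features
#'
#' Two rows per patient: the change vector before the true event (label 1)
#' and before the null event (label 0), with the patient id as the grouping
#' variable for patient-exclusive cross-validation.
#'
#' @param features A `cohort_features` object from [featurize_cohort()].
#' @return list(`x` feature matrix, `y` 0/1 labels, `group` patient ids).
#' @export
build_model_matrix <- function(features) {
  lx_assert(inherits(features, "cohort_features"), "lexicross_shape_error",
            "features must be a cohort_features object")
  tc <- change(features$true_recent, features$true_earlier)
  nc <- change(features$null_recent, features$null_earlier)
  x <- rbind(tc, nc)
  rownames(x) <- NULL
  list(x = x,
       y = rep(c(1L, 0L), each = nrow(tc)),
       group = rep(features$pairs$patient_id, 2L))
}

# Train-fold standardization (sd 0 -> 1 so constant columns pass through).
fit_standardizer <- function(train) {
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' PCA dimensionality reduction fitted on training rows only
#'
#' Orthogonal linear projection (principal components of the training
#' matrix) keeping the smallest number of components whose cumulative
#' explained variance reaches `variance_retained`; the fixed transform is
#' then applied to the test matrix, never refitted.
#'
#' @param train_matrix,test_matrix Numeric matrices with identical columns.
#' @param variance_retained Fraction in (0, 1].
#' @param min_components Lower bound on retained components (some downstream
#'   learners need >= 2).
#' @return list(`train`, `test` reduced matrices, `rotation`, `center`,
#'   `n_components`, `explained_variance`).
#' @export
reduce_dimensions <- function(train_matrix, test_matrix,
                              variance_retained = 0.95,
                              min_components = 1L) {
  lx_assert(variance_retained > 0 && variance_retained <= 1,
            "lexicross_config_error",
            "variance_retained must lie in (0, 1]")
  pc <- stats::prcomp(train_matrix, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v[v > 1e-12]
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_retained - 1e-12)[1]
  if (is.na(k)) k <- length(v)
  k <- min(max(k, min_components), length(v))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  list(train = pc$x[, seq_len(k), drop = FALSE],
       test = scale(test_matrix, center = pc$center, scale = FALSE) %*% rot,
       rotation = rot, center = pc$center, n_components = k,
       explained_variance = cum[k])
}

# ---------------------------------------------------------------------------
# Base learners and the linear ensemble

#' Fit the four-learner probability-averaging ensemble
#'
#' Random forest, radial SVM (Platt probabilities), gradient boosting
#' (xgboost) and plain logistic regression, each with pinned library-default
#' hyperparameters; the ensemble score for a row is the unweighted mean of
#' the four predicted class-1 probabilities. All stochastic components are
#' seeded.
#'
#' @param x Numeric training matrix (standardized / PCA-reduced).
#' @param y 0/1 labels; both classes must be present.
#' @param seed Integer seed.
#' @return Object of class `visit_ensemble`.
#' @export
fit_ensemble <- function(x, y, seed = 1L) {
  y <- as.integer(y)
  lx_assert(length(unique(y)) == 2L, "lexicross_degenerate",
            "training fold holds a single class; cannot fit")
  colnames(x) <- paste0("pc", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0L, 1L))
  rf <- with_seed(derive_seed(seed, 1L),
                  randomForest::randomForest(x, yf, ntree = 500L))
  sv <- with_seed(derive_seed(seed, 2L),
                  e1071::svm(x, yf, probability = TRUE, kernel = "radial",
                             scale = FALSE))
  gb <- with_seed(derive_seed(seed, 3L), xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3L,
                  eta = 0.1, nthread = 1L),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
    nrounds = 100L, verbose = 0L))
  lr <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                        family = stats::binomial()))
  lr_coef <- lr$coefficients
  lr_coef[is.na(lr_coef)] <- 0
  structure(list(rf = rf, svm = sv, gbm = gb, lr_coef = lr_coef),
            class = "visit_ensemble")
}

#' Predict with the ensemble
#'
#' @param object A `visit_ensemble`.
#' @param newx Matrix of rows to score (same columns as training).
#' @param type `"prob"` for the averaged ensemble probability, `"all"` for
#'   the four base-learner probabilities plus the ensemble column.
#' @param ... Unused.
#' @return Numeric vector (`"prob"`) or matrix (`"all"`).
#' @export
predict.visit_ensemble <- function(object, newx, type = c("prob", "all"),
                                   ...) {
  type <- match.arg(type)
  colnames(newx) <- paste0("pc", seq_len(ncol(newx)))
  p_rf <- stats::predict(object$rf, newx, type = "prob")[, "1"]
  p_sv <- attr(stats::predict(object$svm, newx, probability = TRUE),
               "probabilities")[, "1"]
  p_gb <- stats::predict(object$gbm,
                         xgboost::xgb.DMatrix(newx, nthread = 1L))
  p_lr <- stats::plogis(drop(cbind(1, newx) %*% object$lr_coef))
  probs <- cbind(rf = p_rf, svm = p_sv, gbm = p_gb, lr = p_lr)
  ens <- rowMeans(probs)
  if (type == "prob") unname(ens) else cbind(probs, ensemble = ens)
}

fit_ridge <- function(x, y, seed = 1L) {
  lx_assert(length(unique(y)) == 2L, "lexicross_degenerate",
            "training fold holds a single class; cannot fit")
  with_seed(derive_seed(seed, 4L),
            glmnet::cv.glmnet(x, as.integer(y), family = "binomial",
                              alpha = 0, nfolds = 5L))
}

predict_ridge <- function(model, newx) {
  drop(stats::predict(model, newx = newx, s = "lambda.min",
                      type = "response"))
}

# ---------------------------------------------------------------------------
# Patient-exclusive cross-validation

#' Evaluate a forecaster by patient-exclusive k-fold cross-validation
#'
#' Patients (not rows) are partitioned into k folds, so both of a patient's
#' rows land in the same fold and training and test patients are mutually
#' exclusive. Per fold: standardize and PCA-reduce on the training rows
#' only, fit the model, score the held-out rows. Pooled out-of-fold scores
#' give the reported AUC, ROC curve and F1 at the 0.5 threshold; per-fold
#' metrics and their mean are reported alongside.
#'
#' @param x Feature matrix (rows = change vectors).
#' @param y 0/1 labels.
#' @param group Patient id per row.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and learners.
#' @param config A [pipeline_config()] (PCA variance retained).
#' @param model `"ensemble"` or `"ridge"`.
#' @return Object of class `evaluation_report`.
#' @export
grouped_cv_evaluate <- function(x, y, group, k = 5L, seed = 1L,
                                config = pipeline_config(),
                                model = c("ensemble", "ridge")) {
  model <- match.arg(model)
  y <- as.integer(y)
  patients <- unique(group)
  lx_assert(k <= length(patients), "lexicross_config_error",
            "more folds than patients")
  shuffled <- with_seed(derive_seed(seed, 101L), sample(patients))
  fold_of_patient <- stats::setNames(rep(seq_len(k),
                                         length.out = length(shuffled)),
                                     shuffled)
  fold <- fold_of_patient[group]

  scores <- rep(NA_real_, length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    std <- fit_standardizer(x[!test, , drop = FALSE])
    xtr <- apply_standardizer(std, x[!test, , drop = FALSE])
    xte <- apply_standardizer(std, x[test, , drop = FALSE])
    red <- reduce_dimensions(xtr, xte, config$pca_variance_retained,
                             min_components = 2L)
    fold_seed <- derive_seed(seed, 200L + f)
    s <- if (model == "ensemble") {
      predict(fit_ensemble(red$train, y[!test], fold_seed), red$test)
    } else {
      predict_ridge(fit_ridge(red$train, y[!test], fold_seed), red$test)
    }
    scores[test] <- s
    per_fold[[f]] <- data.frame(
      fold = f, n_test = sum(test), n_components = red$n_components,
      auc = compute_auc(s, y[test]), f1 = f1_score(s, y[test]))
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    auc = compute_auc(scores, y),
    f1 = f1_score(scores, y),
    roc = roc_points(scores, y),
    per_fold = per_fold,
    mean_fold_auc = mean(per_fold$auc),
    scores = scores, labels = y,
    fold_of_patient = fold_of_patient,
    model = model, k = as.integer(k), seed = as.integer(seed),
    pca_variance_retained = config$pca_variance_retained
  ), class = "evaluation_report")
}

#' Ridge-penalized logistic control model
#'
#' The active-control analysis: the same patient-exclusive CV protocol with
#' a single ridge-penalized logistic regression instead of the ensemble.
#'
#' @inheritParams grouped_cv_evaluate
#' @return Object of class `evaluation_report`.
#' @export
ridge_logistic_control <- function(x, y, group, k = 5L, seed = 1L,
                                   config = pipeline_config()) {
  grouped_cv_evaluate(x, y, group, k = k, seed = seed, config = config,
                      model = "ridge")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Patient-exclusive %d-fold CV (%s): pooled AUC = %.3f, F1 = %.3f\n",
    x$k, x$model, x$auc, x$f1))
  cat(sprintf("  per-fold AUC: %s (mean %.3f)\n",
              paste(sprintf("%.3f", x$per_fold$auc), collapse = ", "),
              x$mean_fold_auc))
  invisible(x)
}
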