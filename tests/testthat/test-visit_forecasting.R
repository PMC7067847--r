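test_that("AUC follows the Mann-Whitney convention with ties half", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(compute_auc(1:3, c(1, 1, 1)), class = "lexicross_degenerate")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    s <- sample(round(runif(n), 2), n)   # coarse grid forces ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(compute_auc(s, l), oracle_auc(s, l))
  }
  # invariant under strictly monotone transforms of the scores
  s <- runif(30); l <- rep(c(0, 1), 15)
  expect_equal(compute_auc(exp(3 * s) - 1, l), compute_auc(s, l))
})

test_that("ROC points start at (0,0), end at (1,1), integrate to the AUC", {
  set.seed(9)
  s <- round(runif(50), 2)
  l <- rbinom(50, 1, 0.4)
  roc <- roc_points(s, l)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, compute_auc(s, l), tolerance = 1e-9)
})

test_that("F1 at the 0.5 threshold counts TP/FP/FN correctly", {
  expect_equal(f1_score(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.5)
  expect_equal(f1_score(c(0.9, 0.8), c(1, 1)), 1)
  expect_equal(f1_score(c(0.1, 0.2), c(1, 0)), 0)
})

test_that("PCA reduction is fitted on train rows only", {
  set.seed(5)
  # rank-2 structure in 6 columns
  base <- matrix(rnorm(40 * 2), 40, 2)
  train <- base %*% matrix(rnorm(12), 2, 6)
  test <- matrix(rnorm(10 * 6), 10, 6)
  red <- reduce_dimensions(train, test, 0.95)
  expect_equal(red$n_components, 2L)

  # variance_retained = 1 keeps full rank and reconstructs exactly
  full <- matrix(rnorm(15 * 4), 15, 4)
  r1 <- reduce_dimensions(full, full, 1.0)
  expect_equal(r1$n_components, 4L)
  rec <- r1$train %*% t(r1$rotation) +
    matrix(r1$center, 15, 4, byrow = TRUE)
  expect_equal(rec, full, tolerance = 1e-9)

  # the projection is a fixed transform: permuting test rows permutes output
  perm <- sample(10)
  red_p <- reduce_dimensions(train, test[perm, ], 0.95)
  expect_equal(red_p$test, red$test[perm, ])
  expect_equal(red_p$rotation, red$rotation)

  # a test-only outlier cannot touch the train-side transform
  test_out <- test; test_out[1, ] <- 1e6
  red_o <- reduce_dimensions(train, test_out, 0.95)
  expect_identical(red_o$rotation, red$rotation)
  expect_identical(red_o$train, red$train)

  expect_error(reduce_dimensions(train, test, 1.5),
               class = "lexicross_config_error")
})

test_that("the ensemble averages base-learner probabilities", {
  set.seed(6)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.integer(x[, 1] + 0.5 * rnorm(60) > 0)
  m <- fit_ensemble(x, y, seed = 2)
  all_p <- predict(m, x, type = "all")
  expect_equal(all_p[, "ensemble"], rowMeans(all_p[, 1:4]))
  expect_equal(predict(m, x), unname(all_p[, "ensemble"]))
  expect_error(fit_ensemble(x, rep(1L, 60)),
               class = "lexicross_degenerate")
})

test_that("grouped CV keeps patients fold-exclusive and is reproducible", {
  set.seed(12)
  n <- 40
  pid <- sprintf("p%02d", 1:n)
  # separable signal: true rows shifted on 5 features
  x <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  y <- rep(c(1L, 0L), each = n)
  x[y == 1, 1:5] <- x[y == 1, 1:5] + 6
  group <- rep(pid, 2)
  for (seed in c(1, 7, 13)) {
    ev <- grouped_cv_evaluate(x, y, group, k = 5, seed = seed)
    # both rows of a patient share a fold by construction of the report
    f <- ev$fold_of_patient[group]
    expect_true(all(tapply(f, group, function(v) length(unique(v)) == 1)))
    expect_equal(sort(unique(ev$fold_of_patient)), 1:5)
  }
  ev1 <- grouped_cv_evaluate(x, y, group, k = 5, seed = 3)
  ev2 <- grouped_cv_evaluate(x, y, group, k = 5, seed = 3)
  expect_identical(ev1, ev2)
  # wide-margin separable data is ranked perfectly
  expect_equal(ev1$auc, 1.0)
  rc <- ridge_logistic_control(x, y, group, k = 5, seed = 3)
  expect_equal(rc$auc, 1.0)
  expect_error(grouped_cv_evaluate(x, y, group, k = n + 1, seed = 1),
               class = "lexicross_config_error")
})

test_that("shuffling labels within patients destroys the separable signal", {
  set.seed(30)
  n <- 40
  x <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  y <- rep(c(1L, 0L), each = n)
  x[y == 1, 1:5] <- x[y == 1, 1:5] + 6
  group <- rep(sprintf("p%02d", 1:n), 2)
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  y_perm <- y
  y_perm[c(flip, flip)] <- 1L - y[c(flip, flip)]
  ev <- grouped_cv_evaluate(x, y_perm, group, k = 5, seed = 2)
  expect_lt(ev$auc, 0.65)
  expect_gt(ev$auc, 0.35)
})
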