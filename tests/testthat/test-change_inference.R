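test_that("change and diff-of-diff are exact elementwise contrasts", {
  r <- c(a = 0.05, b = 0.02)
  e <- c(a = 0.02, b = 0.02)
  expect_equal(change(r, e), c(a = 0.03, b = 0))
  expect_equal(change(r, r), c(a = 0, b = 0))
  expect_error(change(r, c(x = 1, b = 2)),
               class = "lexicross_name_mismatch")
  tc <- c(a = 0.03); nc <- c(a = 0.01)
  expect_equal(diff_of_diff(tc, nc), c(a = 0.02))
  # antisymmetry
  set.seed(8)
  u <- stats::setNames(rnorm(5), letters[1:5])
  v <- stats::setNames(rnorm(5), letters[1:5])
  expect_equal(diff_of_diff(u, v), -diff_of_diff(v, u))
  # matrix fixture equals scripted subtraction
  m1 <- matrix(rnorm(20), 4, dimnames = list(NULL, letters[1:5]))
  m2 <- matrix(rnorm(20), 4, dimnames = list(NULL, letters[1:5]))
  expect_equal(diff_of_diff(m1, m2), m1 - m2)
})

test_that("paired t-test reproduces the textbook worked example", {
  tt <- paired_t_test(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(tt$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(round(tt$t, 3), 3.873)
  expect_equal(round(tt$p, 4), 0.0305)
  expect_equal(tt$df, 3L)
  # shift invariance
  tt2 <- paired_t_test(c(1, 2, 3, 4) + 10, c(0, 0, 0, 0) + 10)
  expect_equal(tt2$t, tt$t)
  # degenerate inputs are typed errors
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               class = "lexicross_degenerate")
  expect_error(paired_t_test(c(1, 2), c(0, 0)),
               class = "lexicross_degenerate")
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.02, 0.05)),
               c(0.04, 0.05, 0.04, 0.05))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "lexicross_range_error")
})

test_that("paired Cohen's d_z and its CI behave symmetrically", {
  dz <- cohens_d_paired(c(2, 0, 2, 0))
  expect_equal(dz$d, 1 / sd(c(2, 0, 2, 0)))
  expect_equal(round(dz$d, 3), 0.866)
  se <- sqrt(1 / 4 + dz$d^2 / 8)
  expect_equal(dz$ci, dz$d + c(-1, 1) * qnorm(0.975) * se)
  neg <- cohens_d_paired(-c(2, 0, 2, 0))
  expect_equal(neg$d, -dz$d)
  expect_equal(neg$ci, -rev(dz$ci))
  expect_error(cohens_d_paired(rep(1, 5)), class = "lexicross_degenerate")
  # noncentral-t CI brackets the estimate and is near the normal CI
  nct <- cohens_d_paired(rnorm(40, 0.4), ci = "nct")
  expect_true(nct$ci[1] < nct$d && nct$d < nct$ci[2])
})

test_that("the differential table obeys its row invariants", {
  set.seed(21)
  n <- 30
  feats <- c("dict:a", "dict:b", "topic:t1", "meta:flat")
  tc <- matrix(rnorm(n * 4), n, dimnames = list(NULL, feats))
  nc <- matrix(rnorm(n * 4), n, dimnames = list(NULL, feats))
  tc[, 1] <- tc[, 1] + 1          # one real effect
  tc[, 4] <- 5; nc[, 4] <- 5      # zero-variance feature
  tab <- differential_table(tc, nc, alpha = 0.05)
  expect_s3_class(tab, "differential_table")
  expect_equal(nrow(tab), 4L)
  expect_false(tab$testable[tab$feature == "meta:flat"])
  ok <- tab$testable
  expect_true(all(tab$p_bh[ok] >= tab$p_raw[ok]))
  expect_true(all(tab$d_ci_low[ok] <= tab$cohens_d[ok] &
                    tab$cohens_d[ok] <= tab$d_ci_high[ok]))
  expect_true(all(sign(tab$cohens_d[ok]) == sign(tab$mean_diff_of_diff[ok]) |
                    tab$mean_diff_of_diff[ok] == 0))
  expect_true(tab$significant[tab$feature == "dict:a"])
  expect_equal(tab$group, c("style", "style", "topic", "style")
               [match(tab$feature, feats)])
  # increases sorted before decreases, each by descending |d|
  inc <- which(tab$direction[ok] == "increase")
  dec <- which(tab$direction[ok] == "decrease")
  expect_true(all(inc < min(c(dec, Inf))))

  # n < 3 pairs: nothing testable
  tab2 <- differential_table(tc[1:2, ], nc[1:2, ])
  expect_true(all(!tab2$testable))
})

test_that("statistics agree with stats:: reference implementations", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    tt <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
    # d_z identity: t / sqrt(n)
    expect_equal(cohens_d_paired(x - y)$d, tt$t / sqrt(n),
                 tolerance = 1e-12)
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
  }
})
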