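# Per-feature case-crossover inference: change vectors, diff-of-diff
# contrasts, paired t-tests, BH correction, Cohen's d_z and its CI.

#' Language change within one event period
#'
#' Elementwise `recent - earlier`, the within-period change that removes
#' time-invariant differences between individuals.
#'
#' @param recent,earlier Named numeric vectors (or matrices with identical
#'   dimnames) of window features.
#' @return `recent - earlier`, same names/dims.
#' @export
change <- function(recent, earlier) {
  rn <- if (is.matrix(recent)) colnames(recent) else names(recent)
  en <- if (is.matrix(earlier)) colnames(earlier) else names(earlier)
  lx_assert(identical(rn, en) && !is.null(rn), "lexicross_name_mismatch",
            "recent and earlier must carry identical feature names")
  recent - earlier
}

#' Case-crossover contrast (diff-of-diff)
#'
#' The change before the true event minus the change before the null event,
#' per feature; the quantity the paired t-test and Cohen's d_z summarize.
#'
#' @param true_change,null_change Named vectors or matrices from [change()].
#' @return `true_change - null_change`.
#' @export
diff_of_diff <- function(true_change, null_change) {
  change(true_change, null_change)
}

#' Paired two-tailed t-test
#'
#' Classical paired t on the differences `d_i = true_i - null_i`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with a two-tailed p-value from the t
#' distribution on `n - 1` degrees of freedom.
#'
#' @param true_values,null_values Equal-length numeric vectors, one entry per
#'   patient.
#' @return list(`t`, `p`, `df`, `mean_diff`, `n`).
#' @export
paired_t_test <- function(true_values, null_values) {
  lx_assert(length(true_values) == length(null_values),
            "lexicross_shape_error", "paired vectors must have equal length")
  d <- true_values - null_values
  n <- length(d)
  lx_assert(n >= 3L, "lexicross_degenerate",
            "paired t-test needs at least 3 pairs")
  s <- stats::sd(d)
  lx_assert(is.finite(s) && s > 0, "lexicross_degenerate",
            "pairwise differences have zero variance; statistic undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d), n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`p * m / rank`, monotonized by cumulative minima,
#' capped at 1), returned in input order. Delegates to
#' [stats::p.adjust()] after validating the inputs.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  lx_assert(is.numeric(p_values) && all(is.finite(p_values)) &&
              all(p_values >= 0 & p_values <= 1),
            "lexicross_range_error", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Paired Cohen's d (d_z) with 95% CI
#'
#' `d_z = mean(differences) / sd(differences)` (sample sd, n - 1), the
#' standardized effect for a paired design whose numerator is the mean
#' diff-of-diff. The default CI uses the normal-approximation standard error
#' `sqrt(1/n + d^2 / (2n))`; `ci = "nct"` inverts the noncentral t
#' distribution instead. `variant = "av"` rescales to d_av, mean difference
#' over the average of the two arms' standard deviations (needs `true_values`
#' and `null_values`).
#'
#' @param differences Numeric vector of per-patient paired differences.
#' @param conf Confidence level, default 0.95.
#' @param ci `"normal"` or `"nct"`.
#' @param variant `"dz"` (default) or `"av"`.
#' @param true_values,null_values Original paired vectors, only for
#'   `variant = "av"`.
#' @return list(`d`, `ci` = c(low, high), `n`).
#' @export
cohens_d_paired <- function(differences, conf = 0.95,
                            ci = c("normal", "nct"),
                            variant = c("dz", "av"),
                            true_values = NULL, null_values = NULL) {
  ci <- match.arg(ci)
  variant <- match.arg(variant)
  n <- length(differences)
  lx_assert(n >= 3L, "lexicross_degenerate", "need at least 3 differences")
  s <- stats::sd(differences)
  lx_assert(is.finite(s) && s > 0, "lexicross_degenerate",
            "differences have zero variance; d undefined")
  if (variant == "dz") {
    d <- mean(differences) / s
  } else {
    lx_assert(!is.null(true_values) && !is.null(null_values),
              "lexicross_shape_error",
              "variant 'av' needs true_values and null_values")
    d <- mean(differences) /
      ((stats::sd(true_values) + stats::sd(null_values)) / 2)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci == "normal") {
    se <- sqrt(1 / n + d^2 / (2 * n))
    lo <- d - z * se
    hi <- d + z * se
  } else {
    # Exact CI for d_z: invert the noncentral t CDF at t = d * sqrt(n).
    t_obs <- d * sqrt(n)
    a <- (1 - conf) / 2
    bound <- abs(t_obs) + 20
    # pt() warns about pnt precision far in the tails; harmless here
    lo <- suppressWarnings(tryCatch(stats::uniroot(function(ncp)
      stats::pt(t_obs, n - 1L, ncp) - (1 - a),
      c(-bound, bound), tol = 1e-9)$root / sqrt(n),
      error = function(e) -Inf))
    hi <- suppressWarnings(tryCatch(stats::uniroot(function(ncp)
      stats::pt(t_obs, n - 1L, ncp) - a,
      c(-bound, bound), tol = 1e-9)$root / sqrt(n),
      error = function(e) Inf))
  }
  list(d = d, ci = c(lo, hi), n = n)
}

#' Differential language-feature table
#'
#' For every feature, tests whether the change before the true event differs
#' from the change before the null event across patients: paired two-tailed
#' t-test on the per-patient diff-of-diffs, BH correction over all testable
#' features jointly, Cohen's d_z with 95% CI, and the mean diff-of-diff with
#' its own t-based CI. Features whose diff-of-diffs have zero variance (or
#' fewer than 3 pairs) are reported as non-testable rather than dropped.
#'
#' @param true_change,null_change Patient-by-feature change matrices with
#'   identical dimnames (see [change()]).
#' @param alpha BH significance threshold, default 0.05.
#' @param d_variant `"dz"` (default) or `"av"`.
#' @param ci `"normal"` or `"nct"` CI for d.
#' @return Object of class `differential_table` (a data.frame): columns
#'   `feature`, `group`, `n_pairs`, `mean_diff_of_diff`, `mean_ci_low/high`,
#'   `t_statistic`, `p_raw`, `p_bh`, `cohens_d`, `d_ci_low/high`, `testable`,
#'   `significant`, `direction`; rows sorted increases-then-decreases by
#'   descending `|d|`.
#' @export
differential_table <- function(true_change, null_change, alpha = 0.05,
                               d_variant = c("dz", "av"),
                               ci = c("normal", "nct")) {
  d_variant <- match.arg(d_variant)
  ci <- match.arg(ci)
  lx_assert(is.matrix(true_change) && is.matrix(null_change) &&
              identical(dimnames(true_change), dimnames(null_change)),
            "lexicross_name_mismatch",
            "change matrices must have identical dimnames")
  dd <- diff_of_diff(true_change, null_change)
  feats <- colnames(dd)
  n <- nrow(dd)
  rows <- lapply(seq_along(feats), function(j) {
    x <- dd[, j]
    out <- data.frame(
      feature = feats[j],
      group = feature_group(feats[j]),
      n_pairs = n,
      mean_diff_of_diff = mean(x),
      mean_ci_low = NA_real_, mean_ci_high = NA_real_,
      t_statistic = NA_real_, p_raw = NA_real_, p_bh = NA_real_,
      cohens_d = NA_real_, d_ci_low = NA_real_, d_ci_high = NA_real_,
      testable = FALSE, stringsAsFactors = FALSE)
    tt <- tryCatch(paired_t_test(true_change[, j], null_change[, j]),
                   lexicross_degenerate = function(e) NULL)
    if (is.null(tt)) return(out)
    dz <- cohens_d_paired(x, ci = ci, variant = d_variant,
                          true_values = true_change[, j],
                          null_values = null_change[, j])
    half <- stats::qt(0.975, tt$df) * stats::sd(x) / sqrt(n)
    out$mean_ci_low <- tt$mean_diff - half
    out$mean_ci_high <- tt$mean_diff + half
    out$t_statistic <- tt$t
    out$p_raw <- tt$p
    out$cohens_d <- dz$d
    out$d_ci_low <- dz$ci[1]
    out$d_ci_high <- dz$ci[2]
    out$testable <- TRUE
    out
  })
  tab <- do.call(rbind, rows)
  tab$p_bh[tab$testable] <- bh_adjust(tab$p_raw[tab$testable])
  tab$significant <- !is.na(tab$p_bh) & tab$p_bh < alpha
  tab$direction <- ifelse(is.na(tab$cohens_d), NA_character_,
                          ifelse(tab$cohens_d >= 0, "increase", "decrease"))
  inc <- tab$testable & tab$cohens_d >= 0
  ord <- c(which(inc)[order(-abs(tab$cohens_d[inc]))],
           which(!inc & tab$testable)[order(-abs(tab$cohens_d[!inc &
                                                              tab$testable]))],
           which(!tab$testable))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  class(tab) <- c("differential_table", "data.frame")
  tab
}

feature_group <- function(feature) {
  ifelse(startsWith(feature, "topic:"), "topic",
         ifelse(startsWith(feature, "ngram:"), "ngram", "style"))
}

#' @export
print.differential_table <- function(x, n = 10L, ...) {
  cat("Differential language features: ", nrow(x), " features, ",
      sum(x$significant), " significant at BH alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  cols <- c("feature", "cohens_d", "p_bh", "mean_diff_of_diff",
            "d_ci_low", "d_ci_high", "significant")
  print.data.frame(utils::head(as.data.frame(x)[, cols], n), digits = 3)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more)\n", sep = "")
  invisible(x)
}
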