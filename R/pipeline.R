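# Top-level interface: casecross() fits the whole case-crossover analysis
# and returns a classed object with print/summary/coef/plot/predict
# methods; run_pipeline() drives the simulate -> cohort -> featurize ->
# inference/forecast -> report chain from a config and writes auditable
# artifacts with a hashed run manifest.

#' Fit the case-crossover language analysis
#'
#' End-to-end fit for one analysis arm: assembles the paired cohort
#' (true + null event per patient), featurizes the four windows, runs the
#' per-feature diff-of-diff inference (paired t-tests, BH correction,
#' Cohen's d_z) and evaluates the visit forecaster (PCA + four-learner
#' ensemble and the ridge logistic control) by patient-exclusive
#' cross-validation. A final ensemble is fitted on all rows for
#' [predict.casecross()].
#'
#' @param posts Post data.frame (see [read_posts()]).
#' @param events Visit events data.frame (see [read_events()]).
#' @param arm `"ED"` or `"inpatient"`.
#' @param resources A [feature_resources()] bundle.
#' @param config A [pipeline_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `casecross`.
#' @export
casecross <- function(posts, events, arm = c("ED", "inpatient"),
                      resources, config = pipeline_config(),
                      seed = config$rng_seed) {
  arm <- match.arg(arm)
  cohort <- assemble_cohort(posts, events, arm, config,
                            seed = derive_seed(seed, 11L))
  features <- featurize_cohort(posts, cohort, resources, config)
  true_change <- change(features$true_recent, features$true_earlier)
  null_change <- change(features$null_recent, features$null_earlier)
  differential <- differential_table(true_change, null_change, config$alpha)
  mm <- build_model_matrix(features)
  evaluation <- grouped_cv_evaluate(mm$x, mm$y, mm$group, config$cv_folds,
                                    seed = derive_seed(seed, 21L),
                                    config = config)
  control <- ridge_logistic_control(mm$x, mm$y, mm$group, config$cv_folds,
                                    seed = derive_seed(seed, 22L),
                                    config = config)
  std <- fit_standardizer(mm$x)
  xs <- apply_standardizer(std, mm$x)
  red <- reduce_dimensions(xs, xs, config$pca_variance_retained,
                           min_components = 2L)
  full_model <- list(std = std, center = red$center,
                     rotation = red$rotation,
                     ensemble = fit_ensemble(red$train, mm$y,
                                             derive_seed(seed, 31L)))
  structure(list(arm = arm, cohort = cohort, features = features,
                 true_change = true_change, null_change = null_change,
                 differential = differential, evaluation = evaluation,
                 control = control, full_model = full_model,
                 config = config, seed = as.integer(seed)),
            class = "casecross")
}

#' @export
print.casecross <- function(x, ...) {
  cat("Case-crossover language analysis (", x$arm, " arm)\n", sep = "")
  cat("  patients: ", nrow(x$cohort), " (true + null event each)\n",
      sep = "")
  cat(sprintf("  ensemble %d-fold CV: AUC = %.3f, F1 = %.3f\n",
              x$evaluation$k, x$evaluation$auc, x$evaluation$f1))
  cat(sprintf("  ridge control:      AUC = %.3f, F1 = %.3f\n",
              x$control$auc, x$control$f1))
  cat("  significant features (BH alpha = ", x$config$alpha, "): ",
      sum(x$differential$significant), " of ", nrow(x$differential),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.casecross <- function(object, n = 10L, ...) {
  structure(list(fit = object, n = n), class = "summary.casecross")
}

#' @export
print.summary.casecross <- function(x, ...) {
  print(x$fit)
  cat("\nTop differential features:\n")
  print(x$fit$differential, n = x$n)
  invisible(x)
}

#' Per-feature effect sizes of a fitted analysis
#'
#' @param object A `casecross` fit.
#' @param ... Unused.
#' @return Named vector of Cohen's d_z, in the original feature order
#'   (`NA` for non-testable features).
#' @export
coef.casecross <- function(object, ...) {
  d <- object$differential
  stats::setNames(d$cohens_d[match(object$features$feature_names,
                                   d$feature)],
                  object$features$feature_names)
}

#' Plot ROC curves of a fitted analysis
#'
#' Pooled out-of-fold ROC of the ensemble (solid) and the ridge control
#' (dotted), the chance diagonal, and dots marking sensitivity at 10/50/90%
#' false-positive rate.
#'
#' @param x A `casecross` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.casecross <- function(x, ...) {
  roc <- x$evaluation$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l", lwd = 2, col = "firebrick",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s arm: ensemble AUC = %.2f", x$arm,
                                x$evaluation$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::lines(x$control$roc$fpr, x$control$roc$tpr, lty = 3,
                  col = "steelblue")
  at <- vapply(c(0.1, 0.5, 0.9), function(f)
    max(roc$tpr[roc$fpr <= f]), numeric(1))
  graphics::points(c(0.1, 0.5, 0.9), at, pch = 16)
  graphics::legend("bottomright", c("ensemble", "ridge control"),
                   lty = c(1, 3), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(x)
}

#' Score new change vectors with the full-data ensemble
#'
#' @param object A `casecross` fit.
#' @param newdata Matrix of change vectors with the fit's feature columns.
#' @param type `"prob"` or `"all"` (see [predict.visit_ensemble()]).
#' @param ... Unused.
#' @return Predicted probability that each row is a pre-visit change.
#' @export
predict.casecross <- function(object, newdata, type = c("prob", "all"),
                              ...) {
  type <- match.arg(type)
  fn <- object$features$feature_names
  lx_assert(is.matrix(newdata) && all(fn %in% colnames(newdata)),
            "lexicross_name_mismatch",
            "newdata must carry the fit's feature columns")
  xs <- apply_standardizer(object$full_model$std,
                           newdata[, fn, drop = FALSE])
  xr <- scale(xs, center = object$full_model$center, scale = FALSE) %*%
    object$full_model$rotation
  predict(object$full_model$ensemble, xr, type = type)
}

# ---------------------------------------------------------------------------
# Config-driven pipeline

PIPELINE_KEYS <- c("seed", "output_dir", "arm", "simulate", "analysis")
SIMULATE_KEYS <- c("n_patients", "history_days", "posts_per_day_rate",
                   "words_per_post", "visit_type", "event_fraction",
                   "effects")
ANALYSIS_KEYS <- c("alpha", "cv_folds", "pca_variance_retained",
                   "min_posts_per_window", "window_length_days", "gap_days")

validate_pipeline_config <- function(config) {
  lx_assert(is.list(config), "lexicross_schema_error",
            "pipeline config must be a list or YAML file")
  bad <- setdiff(names(config), PIPELINE_KEYS)
  lx_assert(length(bad) == 0, "lexicross_schema_error",
            paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  lx_assert(!is.null(config$seed), "lexicross_schema_error",
            "config key 'seed' is required")
  lx_assert(!is.null(config$simulate$n_patients), "lexicross_schema_error",
            "config key 'simulate.n_patients' is required")
  bad <- setdiff(names(config$simulate), SIMULATE_KEYS)
  lx_assert(length(bad) == 0, "lexicross_schema_error",
            paste0("unknown simulate key(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(names(config$analysis), ANALYSIS_KEYS)
  lx_assert(length(bad) == 0, "lexicross_schema_error",
            paste0("unknown analysis key(s): ", paste(bad, collapse = ", ")))
  invisible(config)
}

#' Demo pipeline configuration
#'
#' A self-contained synthetic run: `n_patients` patients, one ED visit
#' each, and a health-category shift calibrated to an expected d_z of 0.5
#' in the pre-visit month.
#'
#' @param n_patients Cohort size, default 200.
#' @param seed Master seed.
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(n_patients = 200L, seed = 1L) {
  list(seed = as.integer(seed),
       arm = "ED",
       simulate = list(n_patients = as.integer(n_patients),
                       effects = list(health = list(target_d = 0.5))),
       analysis = list(alpha = 0.05))
}

#' Run the full pipeline from a config
#'
#' Stages, in dependency order: simulate the cohort, assemble the paired
#' design, featurize, per-feature differential inference, CV forecasting,
#' and report rendering. Every output file is written under `output_dir`
#' and listed (with md5 hash) in `manifest.json`; re-running the same
#' config reproduces identical outputs.
#'
#' @param config A config list or path to a YAML file. Keys: `seed`
#'   (required), `arm`, `output_dir`, `simulate` (`n_patients` required,
#'   plus generator knobs and `effects`: category -> multiplier or
#'   `list(target_d = ...)`), `analysis` (alpha, cv_folds, ...).
#' @param output_dir Overrides `config$output_dir`; default a tempdir.
#' @return The run manifest (class `run_manifest`), invisibly; its
#'   `fit` attribute carries the [casecross()] object.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  out <- output_dir %||% config$output_dir %||%
    file.path(tempdir(), paste0("lexicross_run_", config$seed))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  arm <- config$arm %||% "ED"
  an <- config$analysis %||% list()
  pcfg <- pipeline_config(
    window_length_days = an$window_length_days %||% 30L,
    gap_days = an$gap_days %||% 15L,
    min_posts_per_window = an$min_posts_per_window %||% 21L,
    cv_folds = an$cv_folds %||% 5L,
    alpha = an$alpha %||% 0.05,
    pca_variance_retained = an$pca_variance_retained %||% 0.95,
    rng_seed = seed)

  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # simulate ----
  res <- default_synthetic_resources()
  sim <- config$simulate
  scfg <- simulation_config(
    n_patients = sim$n_patients,
    history_days = sim$history_days %||% 365L,
    posts_per_day_rate = sim$posts_per_day_rate %||% 1.5,
    words_per_post = sim$words_per_post %||% 12L,
    event_fraction = sim$event_fraction %||% 1,
    visit_type = sim$visit_type %||% arm,
    window_length_days = pcfg$window_length_days,
    gap_days = pcfg$gap_days,
    rng_seed = derive_seed(seed, 1L))
  for (cat in names(sim$effects)) {
    eff <- sim$effects[[cat]]
    scfg$effect_specs[[cat]] <- if (is.list(eff)) {
      calibrate_multiplier(scfg, cat, eff$target_d)
    } else {
      as.numeric(eff)
    }
  }
  cohort_data <- generate_cohort(scfg)
  write_cohort(cohort_data, out)
  timings["simulate"] <- tic() - t0

  # fit (cohort + featurize + inference + forecast) ----
  t0 <- tic()
  fit <- casecross(cohort_data$posts, cohort_data$events, arm,
                   res$resources, pcfg, seed = seed)
  timings["fit"] <- tic() - t0

  # reports ----
  t0 <- tic()
  write_cohort_manifest(fit$cohort, file.path(out, "cohort_manifest.csv"))
  write_feature_matrix(fit$features, file.path(out, "features.csv"),
                       file.path(out, "features_meta.json"))
  render_reports(fit$differential, fit$evaluation, fit$control, out)
  timings["reports"] <- tic() - t0

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    config = config,
    seed = seed,
    arm = arm,
    n_pairs = nrow(fit$cohort),
    injected_truth = cohort_data$truth,
    stage_timings_sec = as.list(round(timings, 3)),
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out, f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(manifest, class = "run_manifest", fit = fit, dir = out)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("lexicross run (seed ", x$seed, ", ", x$arm, " arm): ",
      x$n_pairs, " pairs\n  outputs in ", attr(x, "dir"), ":\n", sep = "")
  for (f in names(x$outputs)) cat("   ", f, "\n")
  invisible(x)
}

write_feature_matrix <- function(features, csv_path, meta_path) {
  slots <- c("true_recent", "true_earlier", "null_recent", "null_earlier")
  rows <- lapply(slots, function(s) {
    m <- features[[s]]
    data.frame(patient_id = rownames(m),
               event = sub("_.*", "", s), window = sub(".*_", "", s),
               m, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_names = features$feature_names,
         n_features = length(features$feature_names),
         resources = "builtin:synthetic"),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Render the differential and forecasting reports
#'
#' Writes `differential_report.csv` (style/dictionary features first, then
#' topics; increases before decreases, each sorted by descending |d|),
#' `roc.csv` (pooled out-of-fold ROC points of the ensemble) and
#' `evaluation.json` (ensemble and control AUC/F1, per-fold metrics).
#'
#' @param differential A [differential_table()].
#' @param evaluation,control_evaluation `evaluation_report` objects
#'   (control may be `NULL`).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
render_reports <- function(differential, evaluation,
                           control_evaluation = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- as.data.frame(differential)
  d <- d[d$testable, , drop = FALSE]
  section <- factor(d$group, levels = c("style", "topic", "ngram"))
  dirn <- factor(d$direction, levels = c("increase", "decrease"))
  d <- d[order(section, dirn, -abs(d$cohens_d)), , drop = FALSE]
  rep_df <- data.frame(
    feature = d$feature, section = d$group, direction = d$direction,
    cohens_d = d$cohens_d, p_corrected = d$p_bh,
    mean_diff_of_diff = d$mean_diff_of_diff,
    ci_low = d$d_ci_low, ci_high = d$d_ci_high,
    significant = d$significant, stringsAsFactors = FALSE)
  utils::write.csv(rep_df, file.path(dir, "differential_report.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$roc, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  ev <- list(ensemble = list(auc = evaluation$auc, f1 = evaluation$f1,
                             mean_fold_auc = evaluation$mean_fold_auc,
                             per_fold = evaluation$per_fold))
  if (!is.null(control_evaluation)) {
    ev$ridge_control <- list(auc = control_evaluation$auc,
                             f1 = control_evaluation$f1,
                             mean_fold_auc = control_evaluation$mean_fold_auc)
    ev$ensemble_minus_control_auc <- evaluation$auc - control_evaluation$auc
  }
  jsonlite::write_json(ev, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
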