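# Paired case-crossover construction: window geometry, true-event selection,
# null-event sampling and cohort assembly. Each patient serves as their own
# control: one true event (the hospital visit) and one null event (a random
# date), each anchoring an earlier/gap/recent window triplet.

#' Lay out the window geometry for one event
#'
#' Given an event date, returns the three disjoint whole-day intervals used
#' throughout the analysis (defaults): `recent` = the 30 days ending the day
#' before the event, a 15-day `gap`, and an `earlier` 30-day window before
#' the gap. The event day itself is excluded.
#'
#' @param event_date A `Date` (or coercible).
#' @param config A [pipeline_config()].
#' @return Object of class `window_pair`: list of `earlier`, `gap`, `recent`,
#'   each a length-2 Date vector of inclusive endpoints.
#' @examples
#' wp <- build_window_pair(as.Date("2014-04-11"), pipeline_config())
#' wp$recent   # 30 days ending the day before the visit
#' @export
build_window_pair <- function(event_date, config = pipeline_config()) {
  event_date <- as.Date(event_date)
  w <- config$window_length_days
  g <- config$gap_days
  recent <- c(event_date - w, event_date - 1L)
  gap <- c(event_date - w - g, event_date - w - 1L)
  earlier <- c(event_date - 2L * w - g, event_date - w - g - 1L)
  structure(list(earlier = earlier, gap = gap, recent = recent,
                 event_date = event_date),
            class = "window_pair")
}

in_interval <- function(dates, interval) {
  dates >= interval[1] & dates <= interval[2]
}

count_posts_in <- function(post_dates, interval) {
  sum(in_interval(post_dates, interval))
}

# Inclusion rule: at least min_posts_per_window posts in BOTH the earlier
# and the recent window of the event's window pair.
meets_inclusion <- function(post_dates, event_date, config) {
  wp <- build_window_pair(event_date, config)
  count_posts_in(post_dates, wp$recent) >= config$min_posts_per_window &&
    count_posts_in(post_dates, wp$earlier) >= config$min_posts_per_window
}

#' Select a patient's true event
#'
#' Scans one patient's visits from most recent to earliest and returns the
#' first whose window pair satisfies the posts-per-window inclusion rule.
#' With `config$strict_recent_only = TRUE` only the most recent visit is
#' considered and the patient is dropped if it fails.
#'
#' @param visits data.frame of this patient's visits (one analysis arm).
#' @param post_dates `Date` vector of this patient's post dates.
#' @param config A [pipeline_config()].
#' @return list(`date`, `visit_type`) or `NULL` if no visit qualifies.
#' @export
select_true_event <- function(visits, post_dates, config = pipeline_config()) {
  if (nrow(visits) == 0L) return(NULL)
  ord <- order(visits$visit_date, decreasing = TRUE)
  candidates <- if (config$strict_recent_only) ord[1L] else ord
  for (i in candidates) {
    if (meets_inclusion(post_dates, visits$visit_date[i], config)) {
      return(list(date = visits$visit_date[i],
                  visit_type = as.character(visits$visit_type[i])))
    }
  }
  NULL
}

#' Sample a patient's null event date
#'
#' Draws candidate dates uniformly from the part of the patient's posting
#' span where a full lookback period (2 windows + gap) exists, and returns
#' the first that (a) satisfies the same posts-per-window inclusion rule as
#' the true event and (b) — unless `config$allow_null_overlap` — has a
#' lookback period disjoint from the true event's. Gives up after
#' `config$max_null_draws` draws.
#'
#' Uses the current RNG stream; seed via [with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param post_dates `Date` vector of the patient's post dates.
#' @param true_event_date The selected true event date.
#' @param config A [pipeline_config()].
#' @return A `Date`, or `NULL` when no feasible null date was found.
#' @export
sample_null_event <- function(post_dates, true_event_date,
                              config = pipeline_config()) {
  if (length(post_dates) == 0L) return(NULL)
  plen <- period_length_days(config)
  lo <- min(post_dates) + plen
  hi <- max(post_dates)
  if (hi < lo) return(NULL)
  span <- as.integer(hi - lo)
  true_period <- c(true_event_date - plen, true_event_date - 1L)
  for (k in seq_len(config$max_null_draws)) {
    cand <- lo + sample.int(span + 1L, 1L) - 1L
    if (!config$allow_null_overlap) {
      cand_period <- c(cand - plen, cand - 1L)
      if (cand_period[1] <= true_period[2] && true_period[1] <= cand_period[2])
        next
    }
    if (meets_inclusion(post_dates, cand, config)) return(cand)
  }
  NULL
}

#' Assemble a paired case-crossover cohort
#'
#' For one analysis arm (ED or inpatient), selects each patient's true event,
#' samples a non-overlapping null event, and returns one event pair per
#' retained patient. Patients failing the inclusion rule (or with no feasible
#' null period) are dropped and logged. True-event selection is deterministic,
#' so re-running with a different seed regenerates an independent control set
#' for the same patients and the same true events.
#'
#' @param posts Post data.frame (see [read_posts()]).
#' @param events Visit data.frame (see [read_events()]).
#' @param arm `"ED"` or `"inpatient"`.
#' @param config A [pipeline_config()].
#' @param seed Seed for null-date sampling; default `config$rng_seed`.
#' @return Object of class `case_cohort`: a data.frame of pairs
#'   (`patient_id`, `true_date`, `visit_type`, `null_date`, and the four
#'   posts-per-window counts) with attributes `arm`, `config` and `dropped`.
#' @export
assemble_cohort <- function(posts, events, arm = c("ED", "inpatient"),
                            config = pipeline_config(),
                            seed = config$rng_seed) {
  arm <- match.arg(arm)
  validate_posts(posts)
  ev <- events[as.character(events$visit_type) == arm, , drop = FALSE]
  post_dates_all <- as.Date(posts$timestamp)
  by_patient <- split(seq_len(nrow(posts)), posts$patient_id)
  patient_ids <- intersect(names(by_patient), unique(ev$patient_id))

  rows <- vector("list", length(patient_ids))
  dropped <- list()
  with_seed(seed, {
    for (i in seq_along(patient_ids)) {
      pid <- patient_ids[i]
      pd <- post_dates_all[by_patient[[pid]]]
      te <- select_true_event(ev[ev$patient_id == pid, , drop = FALSE],
                              pd, config)
      if (is.null(te)) {
        dropped[[pid]] <- "no qualifying visit"
        next
      }
      ne <- sample_null_event(pd, te$date, config)
      if (is.null(ne)) {
        dropped[[pid]] <- "no feasible null period"
        next
      }
      twp <- build_window_pair(te$date, config)
      nwp <- build_window_pair(ne, config)
      rows[[i]] <- data.frame(
        patient_id = pid, true_date = te$date, visit_type = te$visit_type,
        null_date = ne,
        n_true_recent = count_posts_in(pd, twp$recent),
        n_true_earlier = count_posts_in(pd, twp$earlier),
        n_null_recent = count_posts_in(pd, nwp$recent),
        n_null_earlier = count_posts_in(pd, nwp$earlier),
        stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  lx_assert(!is.null(pairs) && nrow(pairs) > 0, "lexicross_empty_cohort",
            paste0("no patient in arm ", arm, " satisfied the design"))
  rownames(pairs) <- NULL
  if (length(dropped))
    lx_log(length(dropped), " patient(s) dropped in arm ", arm)
  structure(pairs, arm = arm, config = config, seed = as.integer(seed),
            dropped = dropped, class = c("case_cohort", "data.frame"))
}

#' @export
print.case_cohort <- function(x, ...) {
  cat("Case-crossover cohort (", attr(x, "arm"), " arm): ",
      nrow(x), " patient pairs, ", length(attr(x, "dropped")),
      " dropped\n", sep = "")
  print.data.frame(utils::head(x, 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more)\n", sep = "")
  invisible(x)
}

#' Write a cohort manifest
#'
#' Audit CSV listing, per retained patient, the true and null event dates and
#' the four posts-per-window counts.
#'
#' @param cohort A `case_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$true_date <- format(df$true_date, "%Y-%m-%d")
  df$null_date <- format(df$null_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
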