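test_that("window geometry follows the 30/15/30 layout excluding the event day", {
  cfg <- pipeline_config()
  d0 <- as.Date("2014-01-01")          # "day 1"
  wp <- build_window_pair(d0 + 99L, cfg)  # event on day 100
  day <- function(x) as.integer(x - d0) + 1L
  expect_equal(day(wp$recent), c(70L, 99L))
  expect_equal(day(wp$gap), c(55L, 69L))
  expect_equal(day(wp$earlier), c(25L, 54L))

  # degenerate geometry: 1-day windows, no gap
  cfg1 <- pipeline_config(window_length_days = 1L, gap_days = 0L)
  wp1 <- build_window_pair(d0, cfg1)
  expect_equal(wp1$recent, c(d0 - 1L, d0 - 1L))
  expect_equal(wp1$earlier, c(d0 - 2L, d0 - 2L))

  # property over random dates: exact lengths, disjoint, event day excluded
  set.seed(11)
  for (d in sample(0:20000, 200)) {
    wp <- build_window_pair(d0 + d, cfg)
    expect_equal(as.integer(wp$recent[2] - wp$recent[1]) + 1L, 30L)
    expect_equal(as.integer(wp$earlier[2] - wp$earlier[1]) + 1L, 30L)
    expect_equal(as.integer(wp$gap[2] - wp$gap[1]) + 1L, 15L)
    expect_true(wp$earlier[2] < wp$gap[1] && wp$gap[2] < wp$recent[1])
    expect_true(wp$recent[2] < d0 + d)
  }
})

test_that("true-event selection scans back to the latest qualifying visit", {
  cfg <- pipeline_config(min_posts_per_window = 3L)
  # dense posting around the early visit only
  early <- as.Date("2014-06-01")
  late <- as.Date("2014-10-01")
  post_dates <- c(early - seq(1, 29, 2), early - 45 - seq(1, 29, 2))
  visits <- data.frame(patient_id = "p1",
                       visit_date = c(early, late),
                       visit_type = factor(c("ED", "ED"),
                                           levels = c("ED", "inpatient")))
  sel <- select_true_event(visits, post_dates, cfg)
  expect_equal(sel$date, early)

  # when the latest also qualifies it wins
  post_dates2 <- c(post_dates, late - seq(1, 29, 2), late - 45 - seq(1, 29, 2))
  expect_equal(select_true_event(visits, post_dates2, cfg)$date, late)

  # strict mode refuses to scan back
  cfg_strict <- pipeline_config(min_posts_per_window = 3L,
                                strict_recent_only = TRUE)
  expect_null(select_true_event(visits, post_dates, cfg_strict))

  # nothing qualifies
  expect_null(select_true_event(visits, post_dates[1:2], cfg))
})

test_that("null events are reproducible, feasible and non-overlapping", {
  cfg <- pipeline_config(min_posts_per_window = 5L)
  # 150 days of daily posting, true event at the last day
  dates <- as.Date("2014-01-01") + 0:149
  true_event <- as.Date("2014-01-01") + 150L

  set.seed(5); n1 <- sample_null_event(dates, true_event, cfg)
  set.seed(5); n2 <- sample_null_event(dates, true_event, cfg)
  expect_identical(n1, n2)
  expect_false(is.null(n1))
  # forced into the head of the history: its 75-day period must end before
  # the true period starts
  expect_true(n1 - 1L < true_event - 75L)

  # an 80-day history cannot host two disjoint 75-day periods
  short <- as.Date("2014-01-01") + 0:79
  set.seed(5)
  expect_null(sample_null_event(short, as.Date("2014-01-01") + 80L, cfg))
})

test_that("cohort assembly pairs every retained patient once and logs drops", {
  cfg <- simulation_config(n_patients = 12, history_days = 200, rng_seed = 3)
  co <- generate_cohort(cfg)
  cohort <- assemble_cohort(co$posts, co$events, "ED", pipeline_config(),
                            seed = 1)
  expect_equal(nrow(cohort), 12L)
  expect_equal(anyDuplicated(cohort$patient_id), 0L)
  expect_true(all(cohort$n_true_recent >= 21 & cohort$n_true_earlier >= 21))
  expect_true(all(cohort$n_null_recent >= 21 & cohort$n_null_earlier >= 21))

  # a new seed changes only the null side
  cohort2 <- assemble_cohort(co$posts, co$events, "ED", pipeline_config(),
                             seed = 2)
  expect_identical(cohort$true_date, cohort2$true_date)
  expect_false(all(cohort$null_date == cohort2$null_date))

  # hand-built 3-patient set where one patient fails inclusion
  mk <- function(pid, dates) make_posts(pid, paste(dates, "10:00:00"), "w")
  ev_date <- as.Date("2014-08-01")
  good <- c(ev_date - 1:25, ev_date - 45 - 1:25,
            ev_date - 150 - 1:25, ev_date - 195 - 1:25)
  posts3 <- rbind(mk("a", good), mk("b", good), mk("c", ev_date - 1:25))
  events3 <- data.frame(patient_id = c("a", "b", "c"), visit_date = ev_date,
                        visit_type = factor("ED",
                                            levels = c("ED", "inpatient")))
  cfg5 <- pipeline_config(min_posts_per_window = 21L)
  ch3 <- assemble_cohort(posts3, events3, "ED", cfg5, seed = 4)
  expect_equal(sort(ch3$patient_id), c("a", "b"))
  expect_named(attr(ch3, "dropped"), "c")

  # empty eligible cohort is a typed error
  expect_error(assemble_cohort(posts3[posts3$patient_id == "c", ],
                               events3[3, ], "ED", cfg5),
               class = "lexicross_empty_cohort")
})
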