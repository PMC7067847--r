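test_that("generation is deterministic and conserves emission probability", {
  cfg <- simulation_config(n_patients = 8, history_days = 160, rng_seed = 42,
                           effect_specs = list(health = 2.5, informal = 0.5))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # different seed, different posts
  cfg2 <- simulation_config(n_patients = 8, history_days = 160,
                            rng_seed = 43,
                            effect_specs = list(health = 2.5))
  expect_false(identical(generate_cohort(cfg)$posts,
                         generate_cohort(cfg2)$posts))
  # adjusted vocabulary still sums to one after multiplicative injection
  expect_equal(sum(lexicross:::adjusted_vocab(cfg)), 1)
})

test_that("infeasible and invalid simulation configs are rejected", {
  expect_error(simulation_config(n_patients = 5, history_days = 100),
               class = "lexicross_config_error")
  expect_error(simulation_config(n_patients = 5,
                                 effect_specs = list(health = -1)),
               class = "lexicross_config_error")
  expect_error(simulation_config(n_patients = 5,
                                 effect_specs = list(nosuchcat = 2)),
               class = "lexicross_config_error")
})

test_that("injected emission probabilities match the closed form", {
  # one category word at baseline 0.01, multiplier 2; shifted probability
  # must equal m*p/(1 + (m-1)*p), checked empirically in the pre-event month
  vocab <- c(target = 0.01, filler = 0.99)
  dict <- category_dictionary(list(cat = "target"))
  cfg <- simulation_config(n_patients = 60, history_days = 160,
                           posts_per_day_rate = 2, words_per_post = 15,
                           background_vocab = vocab, dictionary = dict,
                           effect_specs = list(cat = 2), rng_seed = 9)
  co <- generate_cohort(cfg)
  visit <- co$events$visit_date[match(co$posts$patient_id,
                                      co$events$patient_id)]
  day <- as.Date(co$posts$timestamp)
  inj <- day >= visit - 30 & day <= visit - 1
  toks_inj <- unlist(tokenize(co$posts$text[inj]))
  toks_bg <- unlist(tokenize(co$posts$text[!inj]))
  p_shift <- 2 * 0.01 / (1 + 0.01)
  expect_gt(length(toks_inj), 5e4)
  se_inj <- sqrt(p_shift * (1 - p_shift) / length(toks_inj))
  expect_lt(abs(mean(toks_inj == "target") - p_shift), 3 * se_inj)
  se_bg <- sqrt(0.01 * 0.99 / length(toks_bg))
  expect_lt(abs(mean(toks_bg == "target") - 0.01), 3 * se_bg)
  expect_equal(co$truth$cat$shifted_prob, p_shift)
})

test_that("no-effect cohorts show no pre-event frequency shift", {
  cfg <- simulation_config(n_patients = 120, history_days = 160,
                           rng_seed = 31)
  co <- generate_cohort(cfg)
  visit <- co$events$visit_date[match(co$posts$patient_id,
                                      co$events$patient_id)]
  day <- as.Date(co$posts$timestamp)
  inj <- day >= visit - 30 & day <= visit - 1
  dict <- cfg$dictionary$categories$health
  n_inj <- n_bg <- h_inj <- h_bg <- 0
  toks <- tokenize(co$posts$text)
  for (i in seq_along(toks)) {
    hits <- sum(toks[[i]] %in% dict)
    if (inj[i]) { n_inj <- n_inj + length(toks[[i]]); h_inj <- h_inj + hits }
    else { n_bg <- n_bg + length(toks[[i]]); h_bg <- h_bg + hits }
  }
  pt <- prop.test(c(h_inj, h_bg), c(n_inj, n_bg))
  expect_gt(pt$p.value, 0.01)
})

test_that("the analytic effect-size oracle agrees with brute-force simulation", {
  vocab <- c(target = 0.01, filler = 0.99)
  dict <- category_dictionary(list(cat = "target"))
  base <- simulation_config(n_patients = 5, history_days = 160,
                            posts_per_day_rate = 2, words_per_post = 10,
                            background_vocab = vocab, dictionary = dict,
                            rng_seed = 1)
  expect_equal(expected_effect(base, "cat"), 0)
  expect_error(expected_effect(base, "nope"),
               class = "lexicross_unknown_category")

  cfg <- base
  cfg$effect_specs <- list(cat = 2)
  d_analytic <- expected_effect(cfg, "cat")
  expect_gt(d_analytic, 0)
  # monotone in the multiplier
  ds <- vapply(c(1, 1.5, 2, 4), function(m) {
    c2 <- base; c2$effect_specs <- list(cat = m); expected_effect(c2, "cat")
  }, numeric(1))
  expect_true(all(diff(ds) > 0))

  # brute force: 600 tokens/window binomial windows, 1e4 paired replicates
  set.seed(77)
  n_rep <- 1e4
  p0 <- 0.01
  p1 <- 2 * p0 / (1 + p0)
  draw <- function(p) {
    n <- stats::rpois(n_rep, 600)
    stats::rbinom(n_rep, n, p) / n
  }
  dd <- (draw(p1) - draw(p0)) - (draw(p0) - draw(p0))
  d_sim <- mean(dd) / sd(dd)
  expect_lt(abs(d_analytic - d_sim) / d_sim, 0.10)

  # calibration inverts the oracle
  m <- calibrate_multiplier(base, "cat", 0.3)
  c3 <- base; c3$effect_specs <- list(cat = m)
  expect_equal(expected_effect(c3, "cat"), 0.3, tolerance = 1e-8)
})
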