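# Synthetic patient cohorts: per-patient Poisson post streams over a mixture
# vocabulary, one hospital visit in the feasible tail of each history, and a
# configurable multiplicative shift of chosen dictionary-category emission
# probabilities inside the 30 days before the visit. Because the injected
# effect has a closed-form expected Cohen's d_z, every downstream stage can
# be validated against known truth.

#' Built-in synthetic language resources
#'
#' A deterministic, desk-scale stand-in for the real analysis inputs: a
#' Zipf-weighted background vocabulary (~200 words), an 8-category
#' LIWC-style dictionary over it, a 20-topic topic-word table and five
#' weighted lexica (valence, arousal, anxious, depressed, extraverted).
#' Scaled down from full-size resources (thousands of words, 200 topics) so
#' simulation studies stay fast; the construction is fixed and RNG-free.
#'
#' @return list with `background_vocab` (named probability vector),
#'   `dictionary`, `topics`, `lexicons` and the assembled `resources`
#'   ([feature_resources()]).
#' @export
default_synthetic_resources <- function() {
  cats <- list(
    health = c("pain", "sick", "hospital", "doctor", "tired", "hurt", "ill",
               "meds", "nurse", "surgery"),
    informal = c("lol", "u", "lmao", "smh", "haha", "ya", "tho", "da",
                 ":)", "<3"),
    family = c("baby", "son", "mom", "family", "kids", "daughter", "mother",
               "father"),
    leisure = c("fun", "play", "nap", "game", "movie", "party", "chill",
                "weekend"),
    negemo = c("sad", "cry", "hate", "ugh", "mad", "annoyed", "upset",
               "worst"),
    posemo = c("love", "good", "happy", "great", "blessed", "thankful",
               "amazing", "best"),
    social = c("we", "our", "friends", "friend", "everyone", "together",
               "crew", "y'all"),
    sleep = c("sleep", "bed", "nite", "night", "awake", "dream")
  )
  filler <- c(
    "i", "i'm", "the", "to", "and", "a", "my", "you", "is", "it", "in",
    "me", "of", "for", "on", "that", "this", "so", "be", "with", "just",
    "have", "not", "but", "at", "all", "get", "like", "do", "up", "out",
    "was", "what", "if", "go", "can", "day", "when", "time", "know", "now",
    "got", "about", "one", "your", "am", "will", "no", "see", "need",
    "today", "back", "from", "people", "who", "they", "think", "want",
    "really", "some", "how", "still", "then", "them", "say", "right",
    "going", "why", "off", "work", "feel", "never", "down", "over", "here",
    "even", "way", "take", "had", "come", "again", "make", "tomorrow",
    "new", "her", "him", "she", "he", "been", "would", "could", "should",
    "much", "more", "always", "little", "big", "home", "house", "school",
    "morning", "every", "everything", "something", "nothing", "anyone",
    "because", "thing", "things", "year", "week", "month", "hope", "wish",
    "let", "keep", "give", "made", "done", "said", "told", "call", "phone",
    "talk", "look", "looking", "waiting", "ready", "long", "last", "first",
    "better", "well", "ok", "yes", "man", "girl", "boy", "life", "world"
  )
  # Raw Zipf weights for filler; per-category totals set so baseline
  # category prevalences land in the 1-8% range typical of LIWC counts.
  filler_w <- stats::setNames(1 / (seq_along(filler) + 5), filler)
  cat_totals <- c(health = 0.08, informal = 0.30, family = 0.07,
                  leisure = 0.06, negemo = 0.05, posemo = 0.10,
                  social = 0.12, sleep = 0.05)
  cat_w <- unlist(lapply(names(cats), function(nm) {
    w <- 1 / seq_along(cats[[nm]])
    stats::setNames(cat_totals[[nm]] * w / sum(w), cats[[nm]])
  }))
  vocab <- c(filler_w, cat_w)
  vocab <- vocab / sum(vocab)

  dictionary <- category_dictionary(cats, name = "synthetic")
  r <- seq_along(vocab)
  topics <- topic_table(data.frame(
    topic_id = sprintf("t%02d", c(r %% 20L + 1L, (r + 7L) %% 20L + 1L)),
    word = rep(names(vocab), 2L),
    weight = rep(c(0.7, 0.3), each = length(vocab)),
    stringsAsFactors = FALSE))
  lex_weights <- function(spec) {
    w <- unlist(lapply(names(spec), function(nm)
      stats::setNames(rep(spec[[nm]], length(cats[[nm]])), cats[[nm]])))
    tapply(w, names(w), sum)  # collapse duplicates across categories
  }
  lexicons <- list(
    weighted_lexicon(lex_weights(list(posemo = 1, negemo = -1)), "valence"),
    weighted_lexicon(lex_weights(list(informal = 0.5, leisure = 0.5,
                                      sleep = -0.5)), "arousal"),
    weighted_lexicon(lex_weights(list(negemo = 0.8, health = 0.5)),
                     "anxious"),
    weighted_lexicon(lex_weights(list(negemo = 1, sleep = 0.3,
                                      posemo = -0.5)), "depressed"),
    weighted_lexicon(lex_weights(list(social = 1, informal = 0.5,
                                      leisure = 0.3)), "extraverted")
  )
  list(background_vocab = vocab, dictionary = dictionary, topics = topics,
       lexicons = lexicons,
       resources = feature_resources(dictionary, topics, lexicons))
}

#' Simulation configuration
#'
#' Conditions for [generate_cohort()]. Defaults describe a cohort the
#' analysis design assumes: one year of history per patient, a homogeneous
#' Poisson posting process at 1.5 posts/day (about 45 posts per 30-day
#' window, comfortably above the 21-post inclusion rule), zero-truncated
#' Poisson post lengths with mean 12 words, and one hospital visit per
#' patient drawn uniformly from the last 90 days of history so a full
#' 75-day lookback and a disjoint null period always exist.
#'
#' @param n_patients Number of patients.
#' @param history_days Days of posting history per patient (>= twice the
#'   75-day lookback period).
#' @param posts_per_day_rate Poisson rate of posts per day.
#' @param words_per_post Mean words per post (zero-truncated Poisson).
#' @param background_vocab Named word-probability vector (sums to 1);
#'   default from [default_synthetic_resources()].
#' @param dictionary [category_dictionary()] resolving effect categories to
#'   words; default from [default_synthetic_resources()].
#' @param effect_specs Named list or vector: category -> multiplier (> 0)
#'   applied to that category's word emission probabilities (then
#'   renormalized) for posts dated within the `window_length_days` days
#'   before the patient's visit.
#' @param event_fraction Fraction of patients given a true visit.
#' @param visit_type `"ED"` or `"inpatient"` for the generated events.
#' @param window_length_days,gap_days Window geometry used for injection and
#'   the effect-size oracle (defaults 30/15).
#' @param rng_seed Seed; the whole cohort is deterministic given it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              history_days = 365L,
                              posts_per_day_rate = 1.5,
                              words_per_post = 12L,
                              background_vocab = NULL,
                              dictionary = NULL,
                              effect_specs = list(),
                              event_fraction = 1,
                              visit_type = c("ED", "inpatient"),
                              window_length_days = 30L,
                              gap_days = 15L,
                              rng_seed = 1L) {
  visit_type <- match.arg(visit_type)
  if (is.null(background_vocab) || is.null(dictionary)) {
    res <- default_synthetic_resources()
    background_vocab <- background_vocab %||% res$background_vocab
    dictionary <- dictionary %||% res$dictionary
  }
  lx_assert(is_count(n_patients), "lexicross_config_error",
            "n_patients must be a positive integer")
  lx_assert(abs(sum(background_vocab) - 1) < 1e-9, "lexicross_config_error",
            "background_vocab probabilities must sum to 1 (within 1e-9)")
  plen <- 2L * as.integer(window_length_days) + as.integer(gap_days)
  lx_assert(history_days >= 2L * plen, "lexicross_config_error",
            paste0("history_days must be at least ", 2L * plen,
                   " (twice the lookback period)"))
  effect_specs <- as.list(effect_specs)
  lx_assert(all(vapply(effect_specs, function(m)
    is.numeric(m) && length(m) == 1L && m > 0, TRUE)),
    "lexicross_config_error", "effect multipliers must be positive numbers")
  lx_assert(all(names(effect_specs) %in% names(dictionary$categories)),
            "lexicross_config_error",
            "every effect category must exist in the dictionary")
  lx_assert(event_fraction > 0 && event_fraction <= 1,
            "lexicross_config_error", "event_fraction must lie in (0, 1]")
  structure(list(
    n_patients = as.integer(n_patients),
    history_days = as.integer(history_days),
    posts_per_day_rate = posts_per_day_rate,
    words_per_post = words_per_post,
    background_vocab = background_vocab,
    dictionary = dictionary,
    effect_specs = effect_specs,
    event_fraction = event_fraction,
    visit_type = visit_type,
    window_length_days = as.integer(window_length_days),
    gap_days = as.integer(gap_days),
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

# Emission probabilities with every effect multiplier applied, renormalized.
# A word matched by several shifted categories receives each multiplier.
adjusted_vocab <- function(config) {
  p <- config$background_vocab
  compiled <- compile_dictionary(config$dictionary)
  for (cat in names(config$effect_specs)) {
    mask <- match_mask(names(p), compiled[[cat]])
    p[mask] <- p[mask] * config$effect_specs[[cat]]
  }
  p / sum(p)
}

#' Analytic expected effect size of an injected shift
#'
#' The paired standardized effect (Cohen's d_z) that the configured
#' multiplier implies for a dictionary category's relative-frequency
#' feature, by the delta method. The category relative frequency in a window
#' with `N` tokens is approximately binomial, so with baseline category
#' probability `p0`, shifted probability `p1 = m p0 / (1 + (m - 1) p0)`
#' (renormalization), and `N = window_length x rate x words_per_post`
#' expected tokens per window, the per-patient diff-of-diff has mean
#' `p1 - p0` and variance `(3 p0 (1 - p0) + p1 (1 - p1)) / N` (three null
#' windows and one shifted window), giving
#' `d_z = (p1 - p0) / sqrt((3 p0 (1 - p0) + p1 (1 - p1)) / N)`.
#'
#' @param config A [simulation_config()].
#' @param category Dictionary category name.
#' @return Expected d_z (0 when the category is not shifted).
#' @export
expected_effect <- function(config, category) {
  compiled <- compile_dictionary(config$dictionary)
  lx_assert(category %in% names(compiled), "lexicross_unknown_category",
            paste0("unknown category: ", category))
  mask <- match_mask(names(config$background_vocab), compiled[[category]])
  p0 <- sum(config$background_vocab[mask])
  p1 <- sum(adjusted_vocab(config)[mask])
  n_tokens <- config$window_length_days * config$posts_per_day_rate *
    config$words_per_post
  num <- p1 - p0
  if (num == 0) return(0)
  num / sqrt((3 * p0 * (1 - p0) + p1 * (1 - p1)) / n_tokens)
}

#' Multiplier achieving a target expected effect
#'
#' Inverts [expected_effect()]: finds the emission multiplier for `category`
#' whose analytic expected d_z equals `target_d`.
#'
#' @param config A [simulation_config()] (other effect specs are kept).
#' @param category Dictionary category to shift.
#' @param target_d Desired expected d_z (sign sets direction).
#' @return The multiplier (1 when `target_d` is 0).
#' @export
calibrate_multiplier <- function(config, category, target_d) {
  if (target_d == 0) return(1)
  f <- function(m) {
    cfg <- config
    cfg$effect_specs[[category]] <- m
    expected_effect(cfg, category) - target_d
  }
  interval <- if (target_d > 0) c(1 + 1e-9, 1e3) else c(1e-6, 1 - 1e-9)
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Simulates post streams and visit events under a [simulation_config()]:
#' homogeneous Poisson post times per patient, zero-truncated Poisson post
#' lengths, words drawn from the background vocabulary — except that posts
#' dated within the `window_length_days` days before the patient's visit use
#' the effect-adjusted emission probabilities. Byte-identical output for the
#' same seed.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: list(`posts`, `events`,
#'   `truth`, `config`), where `truth` records each shifted category's
#'   multiplier, baseline and shifted emission probability, and analytic
#'   expected d_z.
#' @export
generate_cohort <- function(config) {
  lx_assert(inherits(config, "simulation_config"), "lexicross_config_error",
            "config must be a simulation_config")
  base_date <- as.POSIXct("2014-01-01 00:00:00")
  h <- config$history_days
  plen <- 2L * config$window_length_days + config$gap_days
  visit_lo <- max(2L * plen, h - 89L)
  lx_assert(visit_lo <= h, "lexicross_config_error",
            "infeasible config: no room for a visit in the history tail")
  with_seed(config$rng_seed, {
    n <- config$n_patients
    ids <- sprintf("p%04d", seq_len(n))
    n_event <- max(1L, round(config$event_fraction * n))
    event_patients <- sort(sample.int(n, n_event))
    visit_day <- rep(NA_integer_, n)
    visit_day[event_patients] <-
      visit_lo + sample.int(h - visit_lo + 1L, n_event, replace = TRUE) - 1L

    n_posts <- stats::rpois(n, config$posts_per_day_rate * h)
    total <- sum(n_posts)
    pat <- rep(seq_len(n), n_posts)
    day <- sample.int(h, total, replace = TRUE)
    secs <- sample.int(86400L, total, replace = TRUE) - 1L

    len <- stats::rpois(total, config$words_per_post)
    while (any(len == 0L)) {
      z <- len == 0L
      len[z] <- stats::rpois(sum(z), config$words_per_post)
    }

    vd <- visit_day[pat]
    injected <- !is.na(vd) & day >= vd - config$window_length_days &
      day <= vd - 1L

    p_bg <- config$background_vocab
    p_adj <- adjusted_vocab(config)
    draw <- function(k, prob) {
      names(prob)[findInterval(stats::runif(k), cumsum(prob)) + 1L]
    }
    tok_inj <- rep(injected, len)
    words <- character(sum(len))
    words[!tok_inj] <- draw(sum(!tok_inj), p_bg)
    if (any(tok_inj)) words[tok_inj] <- draw(sum(tok_inj), p_adj)

    ends <- cumsum(len)
    starts <- ends - len + 1L
    texts <- vapply(seq_len(total), function(i)
      paste(words[starts[i]:ends[i]], collapse = " "), "")

    ts <- base_date + (day - 1L) * 86400 + secs
    posts <- data.frame(patient_id = ids[pat], timestamp = ts, text = texts,
                        stringsAsFactors = FALSE)
    posts <- posts[order(posts$patient_id, posts$timestamp), , drop = FALSE]
    rownames(posts) <- NULL

    events <- data.frame(
      patient_id = ids[event_patients],
      visit_date = as.Date(base_date) + visit_day[event_patients] - 1L,
      visit_type = factor(config$visit_type, levels = c("ED", "inpatient")),
      stringsAsFactors = FALSE)

    compiled <- compile_dictionary(config$dictionary)
    truth <- lapply(names(config$effect_specs), function(cat) {
      mask <- match_mask(names(p_bg), compiled[[cat]])
      list(category = cat, multiplier = config$effect_specs[[cat]],
           baseline_prob = unname(sum(p_bg[mask])),
           shifted_prob = unname(sum(p_adj[mask])),
           expected_d = expected_effect(config, cat))
    })
    names(truth) <- names(config$effect_specs)

    structure(list(posts = posts, events = events, truth = truth,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$config$n_patients, " patients, ",
      nrow(x$posts), " posts, ", nrow(x$events), " visit events\n", sep = "")
  for (tr in x$truth) {
    cat(sprintf("  injected %s x%.3f (expected d_z = %.3f)\n",
                tr$category, tr$multiplier, tr$expected_d))
  }
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Posts as JSON Lines, events as CSV, injected truth as YAML.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(posts = file.path(dir, "posts.jsonl"),
             events = file.path(dir, "events.csv"),
             truth = file.path(dir, "truth.yaml"))
  write_posts(cohort$posts, paths[["posts"]], "jsonl")
  write_events(cohort$events, paths[["events"]])
  yaml::write_yaml(cohort$truth, paths[["truth"]])
  invisible(paths)
}
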