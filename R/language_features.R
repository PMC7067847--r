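# Window featurization: tokenizer, n-gram counts, dictionary relative
# frequencies, topic loadings, weighted-lexicon scores and posting-time meta
# features, concatenated into a named feature vector per window.

EMOTICONS <- c(":)", ":(", ":'(", ";)", ":/", "<3", ":d", ":p")

# Emoticons first so ":)" survives the punctuation split; the letter-final
# ones (":d", ":p") need a boundary lookahead so ":dog" is not an emoticon.
TOKEN_REGEX <- paste0(
  "(:\\)|:\\(|:'\\(|;\\)|:/|<3|:d(?![a-z0-9])|:p(?![a-z0-9]))",
  "|[a-z0-9]+(?:'[a-z0-9]+)*"
)

#' Tokenize post text
#'
#' The reference tokenizer: lowercases, strips URLs, keeps a fixed emoticon
#' set (`:)`, `:(`, `:'(`, `;)`, `:/`, `<3`, `:D`, `:P`) and apostrophe
#' contractions (`i'm`) as single tokens, and otherwise splits on
#' whitespace/punctuation. Behaves like [strsplit()]: returns a list of
#' token vectors, one per input string.
#'
#' @param text Character vector of raw post texts.
#' @return List of character vectors of lowercase tokens.
#' @examples
#' tokenize("I'm so sick :(")[[1]]
#' @export
tokenize <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("https?://\\S+|www\\.\\S+", " ", text)
  out <- regmatches(text, gregexpr(TOKEN_REGEX, text, perl = TRUE))
  lapply(out, function(t) t[nzchar(t)])
}

#' Count contiguous n-grams
#'
#' Counts 1- to `max_n`-grams within each post; grams never span post
#' boundaries. Multi-word grams are joined with `_`.
#'
#' @param tokens A character vector (one post) or a list of character
#'   vectors (one per post).
#' @param max_n Longest gram length, default 3.
#' @return Named integer vector of gram counts.
#' @export
ngram_counts <- function(tokens, max_n = 3L) {
  lx_assert(is_count(max_n), "lexicross_config_error", "max_n must be >= 1")
  if (!is.list(tokens)) tokens <- list(tokens)
  grams <- unlist(lapply(tokens, function(t) {
    len <- length(t)
    if (len == 0L) return(character(0))
    unlist(lapply(seq_len(min(max_n, len)), function(n) {
      do.call(paste, c(lapply(seq_len(n), function(i) t[i:(len - n + i)]),
                       sep = "_"))
    }), use.names = FALSE)
  }), use.names = FALSE)
  if (length(grams) == 0L) return(stats::setNames(integer(0), character(0)))
  u <- unique(grams)
  stats::setNames(tabulate(match(grams, u), nbins = length(u)), u)
}

# Split dictionary patterns into exact tokens and wildcard prefixes once.
compile_dictionary <- function(dictionary) {
  lapply(dictionary$categories, function(p) {
    wild <- endsWith(p, "*")
    list(exact = p[!wild], prefixes = sub("\\*$", "", p[wild]))
  })
}

match_mask <- function(words, compiled_cat) {
  m <- words %in% compiled_cat$exact
  for (pre in compiled_cat$prefixes) m <- m | startsWith(words, pre)
  m
}

#' Dictionary-category relative frequencies
#'
#' For each category, the number of window tokens matching any of its
#' patterns divided by the total number of tokens in the window. Wildcard
#' patterns (`hosp*`) match any token with that prefix; a token matching
#' patterns in several categories counts once in each.
#'
#' @param tokens Character vector of all tokens in one window.
#' @param dictionary A [category_dictionary()].
#' @return Named numeric vector, one relative frequency per category (all 0
#'   for an empty window).
#' @export
dictionary_features <- function(tokens, dictionary) {
  compiled <- compile_dictionary(dictionary)
  total <- length(tokens)
  if (total == 0L)
    return(stats::setNames(numeric(length(compiled)), names(compiled)))
  u <- unique(tokens)
  cnt <- tabulate(match(tokens, u), nbins = length(u))
  vapply(compiled, function(cc) sum(cnt[match_mask(u, cc)]) / total,
         numeric(1))
}

#' Topic loadings of a window
#'
#' Word-level topic mixture: `loading(t) = sum_w freq(w | window) *
#' p(t | w)`, where `p(t | w)` is the topic table's weight for word `w`
#' normalized over topics and `freq(w | window)` is the word's relative
#' frequency among in-vocabulary tokens. The loadings form a probability
#' vector whenever at least one token is in vocabulary; otherwise an
#' all-zero vector is returned with attribute `in_vocab_tokens = 0`.
#'
#' @param tokens Character vector of window tokens.
#' @param topics A [topic_table()].
#' @return Named numeric vector over topic ids with attribute
#'   `in_vocab_tokens`.
#' @export
topic_loadings <- function(tokens, topics) {
  lx_assert(inherits(topics, "topic_table"), "lexicross_resource_error",
            "topics must be a topic_table")
  idx <- match(tokens, topics$words)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    out <- stats::setNames(numeric(topics$n_topics), topics$topic_ids)
    attr(out, "in_vocab_tokens") <- 0L
    return(out)
  }
  cnt <- tabulate(idx, nbins = length(topics$words))
  freq <- cnt / sum(cnt)
  out <- drop(crossprod(topics$p_topic_given_word, freq))
  names(out) <- topics$topic_ids
  attr(out, "in_vocab_tokens") <- length(idx)
  out
}

#' Weighted-lexicon score of a window
#'
#' `intercept + sum_w weight(w) * freq(w | window)` with `freq` relative to
#' the total token count of the window, so duplicating every post leaves the
#' score unchanged. An empty window scores the intercept.
#'
#' @param tokens Character vector of window tokens.
#' @param lexicon A [weighted_lexicon()].
#' @return A single numeric score.
#' @export
lexicon_score <- function(tokens, lexicon) {
  lx_assert(inherits(lexicon, "weighted_lexicon"), "lexicross_resource_error",
            "lexicon must be a weighted_lexicon")
  total <- length(tokens)
  if (total == 0L) return(lexicon$intercept)
  w <- lexicon$weights[match(tokens, names(lexicon$weights))]
  lexicon$intercept + sum(w, na.rm = TRUE) / total
}

META_BIN_NAMES <- sprintf("meta:posts_%02d_%02d", seq(0, 21, 3), seq(3, 24, 3))
META_NAMES <- c(META_BIN_NAMES, "meta:total_posts", "meta:mean_tokens_per_post")

#' Posting-statistics meta features
#'
#' Counts of posts per half-open 3-hour clock bin (eight bins, `[0,3)` to
#' `[21,24)`; a 12:00:00 post falls in the 12-15 bin), the total post count
#' and the mean token count per post.
#'
#' @param timestamps POSIXct vector of post times in the window.
#' @param tokens_per_post Integer vector of token counts, parallel to
#'   `timestamps`.
#' @return Named numeric vector of ten meta features.
#' @export
meta_features <- function(timestamps, tokens_per_post) {
  bins <- numeric(8L)
  if (length(timestamps) > 0L) {
    hours <- as.POSIXlt(timestamps)$hour
    bins <- tabulate(hours %/% 3L + 1L, nbins = 8L)
  }
  mean_tokens <- if (length(tokens_per_post) > 0L) mean(tokens_per_post) else 0
  stats::setNames(c(bins, length(timestamps), mean_tokens), META_NAMES)
}

# ---------------------------------------------------------------------------
# Resources and full-window featurization

#' Bundle feature resources
#'
#' Collects the dictionary, topic table and weighted lexica used by
#' [featurize()], pre-compiles pattern matchers and fixes the feature-name
#' order once, so the same resources always produce identically named and
#' ordered vectors.
#'
#' @param dictionary A [category_dictionary()].
#' @param topics A [topic_table()].
#' @param lexicons List of [weighted_lexicon()] objects.
#' @return Object of class `feature_resources`.
#' @export
feature_resources <- function(dictionary, topics, lexicons) {
  lx_assert(inherits(dictionary, "category_dictionary"),
            "lexicross_resource_error", "dictionary missing or wrong type")
  lx_assert(inherits(topics, "topic_table"),
            "lexicross_resource_error", "topic table missing or wrong type")
  lx_assert(is.list(lexicons) && length(lexicons) > 0 &&
              all(vapply(lexicons, inherits, TRUE, "weighted_lexicon")),
            "lexicross_resource_error", "lexicons missing or wrong type")
  lex_names <- vapply(lexicons, `[[`, "", "name")
  names(lexicons) <- lex_names
  feature_names <- c(
    paste0("dict:", names(dictionary$categories)),
    paste0("topic:", topics$topic_ids),
    paste0("lex:", lex_names),
    META_NAMES
  )
  structure(list(dictionary = dictionary,
                 compiled_dictionary = compile_dictionary(dictionary),
                 topics = topics, lexicons = lexicons,
                 feature_names = feature_names),
            class = "feature_resources")
}

#' Collect one window's posts for featurization
#'
#' @param posts Post data.frame rows falling inside one window.
#' @param role `"earlier"` or `"recent"` (informational).
#' @return Object of class `tokenized_window`: token list (one element per
#'   post, URLs stripped), timestamps and post count.
#' @export
tokenized_window <- function(posts, role = NA_character_) {
  validate_posts(posts)
  tok <- tokenize(posts$text)
  structure(list(tokens = tok, timestamps = posts$timestamp,
                 post_count = nrow(posts), role = role),
            class = "tokenized_window")
}

# Core featurizer over pre-tokenized content (hot path).
featurize_tokens <- function(tokens_flat, timestamps, tokens_per_post,
                             resources, config) {
  total <- length(tokens_flat)
  dict <- if (total == 0L) {
    stats::setNames(numeric(length(resources$compiled_dictionary)),
                    names(resources$compiled_dictionary))
  } else {
    u <- unique(tokens_flat)
    cnt <- tabulate(match(tokens_flat, u), nbins = length(u))
    vapply(resources$compiled_dictionary,
           function(cc) sum(cnt[match_mask(u, cc)]) / total, numeric(1))
  }
  top <- topic_loadings(tokens_flat, resources$topics)
  lex <- vapply(resources$lexicons,
                function(l) lexicon_score(tokens_flat, l), numeric(1))
  meta <- meta_features(timestamps, tokens_per_post)
  out <- c(stats::setNames(dict, paste0("dict:", names(dict))),
           stats::setNames(as.numeric(top), paste0("topic:", names(top))),
           stats::setNames(lex, paste0("lex:", names(lex))),
           meta)
  if (isTRUE(config$include_ngrams) && total > 0L) {
    ng <- ngram_counts(split(tokens_flat,
                             rep(seq_along(tokens_per_post), tokens_per_post)))
    out <- c(out, stats::setNames(as.numeric(ng) / total,
                                  paste0("ngram:", names(ng))))
  }
  attr(out, "degenerate") <- total == 0L
  out
}

#' Featurize one window
#'
#' Concatenates dictionary relative frequencies, topic loadings, lexicon
#' scores and meta features (plus, optionally, raw n-gram relative
#' frequencies) into one named vector with a fixed, stable name order.
#' A pure function of (window, resources): repeated calls are identical.
#'
#' @param window A [tokenized_window()].
#' @param resources A [feature_resources()] bundle.
#' @param config A [pipeline_config()].
#' @return Named numeric feature vector; attribute `degenerate` is `TRUE`
#'   when the window holds no tokens.
#' @export
featurize <- function(window, resources, config = pipeline_config()) {
  lx_assert(inherits(resources, "feature_resources"),
            "lexicross_resource_error",
            "resources must be a feature_resources bundle")
  tokens_per_post <- lengths(window$tokens)
  featurize_tokens(unlist(window$tokens, use.names = FALSE),
                   window$timestamps, tokens_per_post, resources, config)
}

#' Featurize every window of a cohort
#'
#' Tokenizes all posts once, then builds the four per-patient feature
#' matrices (true/null x earlier/recent) for downstream change inference and
#' forecasting.
#'
#' @param posts Post data.frame.
#' @param cohort A `case_cohort` from [assemble_cohort()].
#' @param resources A [feature_resources()] bundle.
#' @param config A [pipeline_config()].
#' @return Object of class `cohort_features`: list with matrices
#'   `true_recent`, `true_earlier`, `null_recent`, `null_earlier`
#'   (patients x features), `feature_names` and the cohort `pairs`.
#' @export
featurize_cohort <- function(posts, cohort, resources,
                             config = attr(cohort, "config") %||%
                               pipeline_config()) {
  validate_posts(posts)
  tok <- tokenize(posts$text)
  ntok <- lengths(tok)
  post_dates <- as.Date(posts$timestamp)
  by_patient <- split(seq_len(nrow(posts)), posts$patient_id)
  n <- nrow(cohort)
  slots <- c("true_recent", "true_earlier", "null_recent", "null_earlier")
  first <- featurize_tokens(character(0), posts$timestamp[0], integer(0),
                            resources, config)
  p <- length(first)
  mats <- lapply(slots, function(s)
    matrix(NA_real_, n, p, dimnames = list(cohort$patient_id, names(first))))
  names(mats) <- slots
  for (i in seq_len(n)) {
    idx <- by_patient[[cohort$patient_id[i]]]
    twp <- build_window_pair(cohort$true_date[i], config)
    nwp <- build_window_pair(cohort$null_date[i], config)
    wins <- list(true_recent = twp$recent, true_earlier = twp$earlier,
                 null_recent = nwp$recent, null_earlier = nwp$earlier)
    for (s in slots) {
      sel <- idx[in_interval(post_dates[idx], wins[[s]])]
      fv <- featurize_tokens(unlist(tok[sel], use.names = FALSE),
                             posts$timestamp[sel], ntok[sel],
                             resources, config)
      mats[[s]][i, ] <- fv[names(first)]
    }
  }
  structure(list(true_recent = mats$true_recent,
                 true_earlier = mats$true_earlier,
                 null_recent = mats$null_recent,
                 null_earlier = mats$null_earlier,
                 feature_names = names(first),
                 pairs = cohort, config = config),
            class = "cohort_features")
}
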