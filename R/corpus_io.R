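# Readers/writers for posts, visit events, category dictionaries, topic
# tables and weighted lexica, plus the shared pipeline configuration.

#' Pipeline configuration
#'
#' Collects every tunable of the case-crossover analysis in one validated
#' list.  Defaults encode the canonical design: two 30-day windows separated
#' by a 15-day gap, at least 21 posts ("more than 20") in both the earlier
#' and the recent window, a 5-fold patient-exclusive cross-validation, and
#' BH-corrected paired t-tests at alpha = 0.05.
#'
#' @param window_length_days Length of the earlier and recent windows, days.
#' @param gap_days Gap between the two windows, days.
#' @param min_posts_per_window Inclusion rule: minimum posts required in each
#'   of the two windows. The default 21 is the strict reading of
#'   "more than 20 posts".
#' @param n_topics Number of topics expected in a topic table (200 for the
#'   full-scale topic model; synthetic runs use fewer).
#' @param cv_folds Number of cross-validation folds.
#' @param alpha Significance threshold applied to BH-adjusted p-values.
#' @param pca_variance_retained Cumulative explained-variance fraction the
#'   PCA reduction must reach, in (0, 1].
#' @param rng_seed Default seed for every stochastic step.
#' @param strict_recent_only If `TRUE`, a patient whose most recent visit
#'   fails the inclusion rule is dropped; if `FALSE` (default) earlier visits
#'   are scanned until one qualifies.
#' @param allow_null_overlap If `TRUE`, the null event's 75-day period may
#'   overlap the true event's period. Default `FALSE`: overlap would leak
#'   case-window language into the control.
#' @param max_null_draws Number of candidate null dates tried before a
#'   patient is declared infeasible.
#' @param include_ngrams If `TRUE`, raw 1-3-gram relative frequencies are
#'   appended to the feature vector (excluded from the default model matrix;
#'   open-vocabulary signal enters through topic loadings).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_length_days = 30L,
                            gap_days = 15L,
                            min_posts_per_window = 21L,
                            n_topics = 200L,
                            cv_folds = 5L,
                            alpha = 0.05,
                            pca_variance_retained = 0.95,
                            rng_seed = 1L,
                            strict_recent_only = FALSE,
                            allow_null_overlap = FALSE,
                            max_null_draws = 200L,
                            include_ngrams = FALSE) {
  lx_assert(is_count(window_length_days), "lexicross_config_error",
            "window_length_days must be a positive integer")
  lx_assert(is.numeric(gap_days) && length(gap_days) == 1L && gap_days >= 0 &&
              gap_days == as.integer(gap_days),
            "lexicross_config_error", "gap_days must be a nonnegative integer")
  lx_assert(is_count(min_posts_per_window), "lexicross_config_error",
            "min_posts_per_window must be a positive integer")
  lx_assert(is_count(n_topics), "lexicross_config_error",
            "n_topics must be a positive integer")
  lx_assert(is_count(cv_folds), "lexicross_config_error",
            "cv_folds must be a positive integer")
  lx_assert(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1,
            "lexicross_config_error", "alpha must lie in (0, 1)")
  lx_assert(is.numeric(pca_variance_retained) &&
              length(pca_variance_retained) == 1L &&
              pca_variance_retained > 0 && pca_variance_retained <= 1,
            "lexicross_config_error",
            "pca_variance_retained must lie in (0, 1]")
  lx_assert(is_count(max_null_draws), "lexicross_config_error",
            "max_null_draws must be a positive integer")
  structure(list(
    window_length_days = as.integer(window_length_days),
    gap_days = as.integer(gap_days),
    min_posts_per_window = as.integer(min_posts_per_window),
    n_topics = as.integer(n_topics),
    cv_folds = as.integer(cv_folds),
    alpha = alpha,
    pca_variance_retained = pca_variance_retained,
    rng_seed = as.integer(rng_seed),
    strict_recent_only = isTRUE(strict_recent_only),
    allow_null_overlap = isTRUE(allow_null_overlap),
    max_null_draws = as.integer(max_null_draws),
    include_ngrams = isTRUE(include_ngrams)
  ), class = "pipeline_config")
}

# Total span of one event's lookback period: earlier + gap + recent.
period_length_days <- function(config) {
  2L * config$window_length_days + config$gap_days
}

# ---------------------------------------------------------------------------
# Timestamps

# ISO-8601 date-times, with or without a time-of-day. Date-only stamps get
# 12:00 so they land in a defined posting-time bin. Returns POSIXct with NA
# for rows that parse under no accepted layout.
parse_timestamps <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01")
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(date_only)) {
    d <- as.Date(x[date_only], format = "%Y-%m-%d")
    out[date_only] <- as.POSIXct(paste(format(d), "12:00:00"))
  }
  rest <- !date_only & !is.na(x) & nzchar(x)
  if (any(rest)) {
    y <- sub("T", " ", x[rest], fixed = TRUE)
    p <- as.POSIXct(y, format = "%Y-%m-%d %H:%M:%S")
    miss <- is.na(p)
    if (any(miss)) p[miss] <- as.POSIXct(y[miss], format = "%Y-%m-%d %H:%M")
    out[rest] <- p
  }
  out
}

validate_posts <- function(posts) {
  lx_assert(is.data.frame(posts) &&
              all(c("patient_id", "timestamp", "text") %in% names(posts)),
            "lexicross_format_error",
            "posts must have columns patient_id, timestamp, text")
  invisible(posts)
}

#' Read timestamped post records
#'
#' Reads per-patient posts from JSON Lines (one object per line) or CSV with
#' header `patient_id,timestamp,text`. Rows with unparseable timestamps are
#' rejected with a row-number diagnostic; a missing required column aborts.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A data.frame with columns `patient_id` (character), `timestamp`
#'   (POSIXct) and `text` (character), sorted by (patient_id, timestamp).
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  lx_assert(file.exists(path), "lexicross_io_error",
            paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("no post records in ", path, call. = FALSE)
      return(empty_posts())
    }
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    bad_json <- vapply(recs, is.null, logical(1))
    if (any(bad_json)) {
      lx_log(sum(bad_json), " malformed JSONL row(s) skipped (rows ",
             paste(utils::head(which(bad_json), 5L), collapse = ", "), " ...)")
    }
    recs <- recs[!bad_json]
    has_cols <- vapply(recs, function(r)
      all(c("patient_id", "timestamp", "text") %in% names(r)), logical(1))
    lx_assert(all(has_cols) || length(recs) == 0L, "lexicross_format_error",
              "JSONL records must carry patient_id, timestamp and text")
    df <- data.frame(
      patient_id = vapply(recs, function(r) as.character(r$patient_id), ""),
      timestamp = vapply(recs, function(r) as.character(r$timestamp), ""),
      text = vapply(recs, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    if (nrow(df) == 0L) {
      warning("no post records in ", path, call. = FALSE)
      return(empty_posts())
    }
    validate_posts(df)
    df <- df[, c("patient_id", "timestamp", "text")]
  }
  ts <- parse_timestamps(df$timestamp)
  bad <- is.na(ts)
  if (any(bad)) {
    lx_log("rejecting ", sum(bad), " row(s) with unparseable timestamps (rows ",
           paste(utils::head(which(bad), 5L), collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  out <- data.frame(patient_id = df$patient_id, timestamp = ts,
                    text = df$text, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_posts <- function() {
  data.frame(patient_id = character(0),
             timestamp = as.POSIXct(character(0)),
             text = character(0), stringsAsFactors = FALSE)
}

#' Write post records
#'
#' Inverse of [read_posts()]; timestamps are serialized as ISO-8601 with a
#' time-of-day so a round trip preserves every field.
#'
#' @param posts Post data.frame (`patient_id`, `timestamp`, `text`).
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_posts(posts)
  stamp <- format(posts$timestamp, "%Y-%m-%dT%H:%M:%S")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(posts)), function(i) {
      jsonlite::toJSON(list(patient_id = posts$patient_id[i],
                            timestamp = stamp[i],
                            text = posts$text[i]), auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(
      data.frame(patient_id = posts$patient_id, timestamp = stamp,
                 text = posts$text, stringsAsFactors = FALSE),
      path, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Visit events

#' Read hospital-visit events
#'
#' CSV with header `patient_id,visit_date,visit_type`; `visit_type` must be
#' `ED` (emergency visit without admission) or `inpatient`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with `patient_id` (character), `visit_date` (Date) and
#'   `visit_type` (factor with levels ED, inpatient).
#' @export
read_events <- function(path) {
  lx_assert(file.exists(path), "lexicross_io_error",
            paste0("file not found: ", path))
  df <- utils::read.csv(path, colClasses = "character")
  lx_assert(all(c("patient_id", "visit_date", "visit_type") %in% names(df)),
            "lexicross_format_error",
            "events must have columns patient_id, visit_date, visit_type")
  bad_type <- !df$visit_type %in% c("ED", "inpatient")
  lx_assert(!any(bad_type), "lexicross_format_error",
            paste0("unknown visit_type: ",
                   paste(unique(df$visit_type[bad_type]), collapse = ", ")))
  d <- as.Date(df$visit_date, format = "%Y-%m-%d")
  lx_assert(!anyNA(d), "lexicross_format_error",
            "visit_date must be ISO-8601 (YYYY-MM-DD)")
  data.frame(patient_id = df$patient_id, visit_date = d,
             visit_type = factor(df$visit_type, levels = c("ED", "inpatient")),
             stringsAsFactors = FALSE)
}

#' Write hospital-visit events
#' @param events Event data.frame as returned by [read_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    data.frame(patient_id = events$patient_id,
               visit_date = format(events$visit_date, "%Y-%m-%d"),
               visit_type = as.character(events$visit_type),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Category dictionaries

#' Construct a category dictionary
#'
#' A closed-vocabulary (LIWC-style) dictionary: named categories, each a set
#' of lowercase patterns that are either literal tokens or stems with one
#' trailing `*` wildcard (prefix match).
#'
#' @param categories Named list of character pattern vectors.
#' @param name Dictionary name.
#' @return Object of class `category_dictionary`.
#' @export
category_dictionary <- function(categories, name = "dictionary") {
  lx_assert(is.list(categories) && length(categories) > 0 &&
              !is.null(names(categories)) && all(nzchar(names(categories))),
            "lexicross_format_error", "categories must be a named list")
  categories <- lapply(categories, function(p) {
    p <- tolower(as.character(p))
    bad <- grepl("\\*", sub("\\*$", "", p))
    lx_assert(!any(bad), "lexicross_pattern_error",
              paste0("wildcard only allowed as final character: ",
                     paste(p[bad], collapse = ", ")))
    unique(p)
  })
  lx_assert(all(vapply(categories, length, 0L) > 0),
            "lexicross_format_error", "every category must be nonempty")
  structure(list(name = name, categories = categories),
            class = "category_dictionary")
}

#' Read a category dictionary
#'
#' Accepts the LIWC-style `.dic` layout (a `%`-delimited header block mapping
#' numeric category ids to names, then `word<TAB>id ...` lines) or a 2-column
#' CSV `category,pattern`. Patterns are lowercased and duplicates collapsed.
#'
#' @param path Path to the dictionary file.
#' @return Object of class `category_dictionary`.
#' @export
read_dictionary <- function(path) {
  lx_assert(file.exists(path), "lexicross_io_error",
            paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (any(trimws(lines) == "%")) {
    marks <- which(trimws(lines) == "%")
    lx_assert(length(marks) >= 2L, "lexicross_format_error",
              ".dic header must be delimited by two % lines")
    header <- lines[(marks[1] + 1L):(marks[2] - 1L)]
    header <- header[nzchar(trimws(header))]
    parts <- strsplit(trimws(header), "[ \t]+")
    ids <- vapply(parts, `[`, "", 1L)
    nms <- vapply(parts, `[`, "", 2L)
    body <- lines[(marks[2] + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    cats <- stats::setNames(vector("list", length(nms)), nms)
    for (ln in body) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      w <- tolower(f[1])
      for (id in f[-1]) {
        nm <- nms[match(id, ids)]
        lx_assert(!is.na(nm), "lexicross_format_error",
                  paste0("unknown category id in .dic body: ", id))
        cats[[nm]] <- c(cats[[nm]], w)
      }
    }
    cats <- cats[vapply(cats, length, 0L) > 0]
    return(category_dictionary(cats, name = basename(path)))
  }
  df <- utils::read.csv(path, colClasses = "character")
  lx_assert(all(c("category", "pattern") %in% names(df)),
            "lexicross_format_error",
            "dictionary CSV must have columns category, pattern")
  category_dictionary(split(df$pattern, df$category), name = basename(path))
}

# ---------------------------------------------------------------------------
# Topic tables

#' Construct a topic table
#'
#' Topic-word weights from a pre-fitted topic model (e.g. LDA). The per-word
#' conditional topic distribution p(topic | word) is the word's weights
#' normalized over topics; [topic_loadings()] mixes these by in-window word
#' frequency.
#'
#' @param entries data.frame with columns `topic_id`, `word`, `weight`
#'   (nonnegative).
#' @return Object of class `topic_table` with elements `entries`, `n_topics`,
#'   `topic_ids`, `words` and the row-normalized matrix `p_topic_given_word`.
#' @export
topic_table <- function(entries) {
  lx_assert(is.data.frame(entries) &&
              all(c("topic_id", "word", "weight") %in% names(entries)),
            "lexicross_format_error",
            "topic table needs columns topic_id, word, weight")
  w <- as.numeric(entries$weight)
  lx_assert(all(is.finite(w)) && all(w >= 0), "lexicross_format_error",
            "topic weights must be nonnegative")
  entries <- data.frame(topic_id = as.character(entries$topic_id),
                        word = tolower(as.character(entries$word)),
                        weight = w, stringsAsFactors = FALSE)
  entries <- entries[entries$weight > 0, , drop = FALSE]
  lx_assert(nrow(entries) > 0, "lexicross_format_error",
            "topic table has no positive weights")
  ids <- sort(unique(entries$topic_id))
  words <- sort(unique(entries$word))
  m <- matrix(0, nrow = length(words), ncol = length(ids),
              dimnames = list(words, ids))
  m[cbind(match(entries$word, words), match(entries$topic_id, ids))] <-
    entries$weight
  m <- m / rowSums(m)
  structure(list(entries = entries, n_topics = length(ids),
                 topic_ids = ids, words = words, p_topic_given_word = m),
            class = "topic_table")
}

#' Read a topic-word weight table
#'
#' CSV with header `topic_id,word,weight`; negative weights are an error.
#'
#' @param path Path to the CSV file.
#' @return Object of class `topic_table`.
#' @export
read_topic_table <- function(path) {
  lx_assert(file.exists(path), "lexicross_io_error",
            paste0("file not found: ", path))
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  topic_table(df)
}

# ---------------------------------------------------------------------------
# Weighted lexica

#' Construct a weighted lexicon
#'
#' A word-to-weight table whose frequency-weighted sum scores a construct
#' (valence, arousal, anxiety, depression, extraversion).
#'
#' @param weights Named numeric vector of word weights.
#' @param name Lexicon name.
#' @param intercept Additive constant, default 0.
#' @return Object of class `weighted_lexicon`.
#' @export
weighted_lexicon <- function(weights, name = "lexicon", intercept = 0) {
  lx_assert(is.numeric(weights) && length(weights) > 0 &&
              !is.null(names(weights)) && any(weights != 0),
            "lexicross_format_error",
            "lexicon needs a named numeric vector with a nonzero weight")
  names(weights) <- tolower(names(weights))
  structure(list(name = name, weights = weights,
                 intercept = as.numeric(intercept)),
            class = "weighted_lexicon")
}

#' Read a weighted lexicon
#'
#' CSV with header `word,weight`; an optional row with word `(intercept)`
#' sets the additive constant.
#'
#' @param path Path to the CSV file.
#' @param name Lexicon name; defaults to the file stem.
#' @return Object of class `weighted_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL) {
  lx_assert(file.exists(path), "lexicross_io_error",
            paste0("file not found: ", path))
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  lx_assert(all(c("word", "weight") %in% names(df)),
            "lexicross_format_error",
            "lexicon CSV must have columns word, weight")
  ic <- df$word == "(intercept)"
  intercept <- if (any(ic)) sum(df$weight[ic]) else 0
  df <- df[!ic, , drop = FALSE]
  weighted_lexicon(stats::setNames(df$weight, df$word),
                   name = name %||% sub("\\.[^.]*$", "", basename(path)),
                   intercept = intercept)
}
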