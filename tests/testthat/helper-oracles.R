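# Independent reference implementations used to cross-check the package's
# statistical core, plus small shared builders. These deliberately use
# different algorithms (brute force, textbook formulas) than the package.

# BH step-up by the definition: sort, p * m / rank, monotonize from the
# largest rank downward by cumulative minimum, cap at 1, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# AUC by exhaustive pairwise comparison (ties half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Textbook paired t from sum formulas (different arithmetic path).
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  s2 <- (sum(d^2) - sum(d)^2 / n) / (n - 1)
  t <- (sum(d) / n) / sqrt(s2 / n)
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "lexicross", mustWork = TRUE)
}

# Small shared resource bundle for feature tests.
tiny_resources <- function() {
  feature_resources(
    read_dictionary(fixture_path("tiny_dict.csv")),
    read_topic_table(fixture_path("tiny_topics.csv")),
    list(read_lexicon(fixture_path("tiny_lexicon.csv"), name = "mood"))
  )
}

# Posts data.frame builder.
make_posts <- function(patient_id, timestamp, text) {
  data.frame(patient_id = patient_id,
             timestamp = as.POSIXct(timestamp),
             text = text, stringsAsFactors = FALSE)
}
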