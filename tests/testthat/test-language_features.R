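test_that("tokenizer lowercases, keeps emoticons/contractions, strips URLs", {
  expect_equal(tokenize("I'm so sick :(")[[1]], c("i'm", "so", "sick", ":("))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("LOL Lol lol")[[1]], c("lol", "lol", "lol"))
  expect_equal(tokenize("see https://ex.com/a?b=1 now")[[1]], c("see", "now"))
  expect_equal(tokenize("love <3 u :D")[[1]], c("love", "<3", "u", ":d"))
  # ":d" boundary: a word starting with d after a colon is not an emoticon
  expect_equal(tokenize(":dog")[[1]], c("dog"))
  expect_equal(tokenize("well,done!ok")[[1]], c("well", "done", "ok"))
})

test_that("n-gram counts never span post boundaries", {
  expect_equal(ngram_counts(c("a", "b", "c")),
               c(a = 1L, b = 1L, c = 1L, a_b = 1L, b_c = 1L, a_b_c = 1L))
  expect_equal(ngram_counts("solo"), c(solo = 1L))
  expect_equal(ngram_counts(list("a", "b")), c(a = 1L, b = 1L))
  # brute-force enumeration oracle on a random token stream
  set.seed(3)
  toks <- sample(letters[1:4], 30, replace = TRUE)
  got <- ngram_counts(toks)
  for (n in 1:3) {
    grams <- vapply(seq_len(30 - n + 1),
                    function(i) paste(toks[i:(i + n - 1)], collapse = "_"), "")
    for (g in unique(grams)) expect_equal(got[[g]], sum(grams == g))
  }
})

test_that("dictionary relative frequencies implement wildcard and overlap rules", {
  dict <- category_dictionary(list(health = c("sick", "hosp*"),
                                   feelings = c("sick", "happy")))
  toks <- c(rep("filler", 95), rep("sick", 3), "hospital", "happy")
  f <- dictionary_features(toks, dict)
  expect_equal(f[["health"]], 0.04)    # 3 sick + 1 hospital over 100
  expect_equal(f[["feelings"]], 0.04)  # sick counts once in each category
  expect_equal(dictionary_features(character(0), dict),
               c(health = 0, feelings = 0))
})

test_that("topic loadings are the word-level mixture and sum to one", {
  tt <- topic_table(data.frame(topic_id = c("t1", "t1", "t2"),
                               word = c("alpha", "beta", "beta"),
                               weight = c(1, 0.6, 0.2)))
  l1 <- topic_loadings("alpha", tt)
  expect_equal(as.numeric(l1), c(1, 0))
  # hand-computed two-word mixture: p(t1|beta) = .75; freq alpha 2/3, beta 1/3
  l2 <- topic_loadings(c("alpha", "alpha", "beta"), tt)
  expect_equal(as.numeric(l2), c(2 / 3 + 0.75 / 3, 0.25 / 3))
  expect_equal(sum(l2), 1)
  l0 <- topic_loadings(c("out", "of", "vocab"), tt)
  expect_equal(as.numeric(l0), c(0, 0))
  expect_equal(attr(l0, "in_vocab_tokens"), 0L)
})

test_that("lexicon scores are intercept plus frequency-weighted sums", {
  lx <- weighted_lexicon(c(sick = 2, happy = -1), "mood")
  expect_equal(lexicon_score(c("sick", "sick", "happy"), lx), 1.0)
  expect_equal(lexicon_score(c("none", "match"), lx), 0)
  lx2 <- weighted_lexicon(c(sick = 2), "m", intercept = 0.5)
  expect_equal(lexicon_score(character(0), lx2), 0.5)
  # scale invariance: duplicating every token leaves the score unchanged
  toks <- c("sick", "filler", "happy", "sick")
  expect_equal(lexicon_score(rep(toks, 2), lx), lexicon_score(toks, lx))
})

test_that("meta features bin posting times into half-open 3-hour bins", {
  ts <- as.POSIXct(c("2014-01-01 09:30:00", "2014-01-01 13:00:00"))
  m <- meta_features(ts, c(5L, 7L))
  expect_equal(m[["meta:posts_09_12"]], 1)
  expect_equal(m[["meta:posts_12_15"]], 1)
  expect_equal(m[["meta:total_posts"]], 2)
  expect_equal(m[["meta:mean_tokens_per_post"]], 6)
  # boundary: exactly 12:00:00 belongs to the 12-15 bin
  b <- meta_features(as.POSIXct("2014-01-01 12:00:00"), 3L)
  expect_equal(b[["meta:posts_12_15"]], 1)
  expect_equal(b[["meta:posts_09_12"]], 0)
  z <- meta_features(as.POSIXct(character(0)), integer(0))
  expect_true(all(z == 0))
})

test_that("featurize is pure, stably named, and invariant to post duplication", {
  res <- tiny_resources()
  posts <- make_posts("p1",
                      c("2014-01-01 10:00:00", "2014-01-02 22:30:00"),
                      c("sick pain hospital lol", "happy u :) lol the"))
  w <- tokenized_window(posts, "recent")
  f1 <- featurize(w, res)
  f2 <- featurize(w, res)
  expect_identical(f1, f2)
  # arity: categories + topics + lexica + 10 meta
  expect_length(f1, 2 + 2 + 1 + 10)
  expect_identical(names(f1), res$feature_names)

  # duplicating every post: relative-frequency features unchanged
  wd <- tokenized_window(rbind(posts, posts), "recent")
  fd <- featurize(wd, res)
  rel <- grep("^(dict:|topic:|lex:)", names(f1), value = TRUE)
  expect_equal(fd[rel], f1[rel])
  expect_equal(fd[["meta:total_posts"]], 2 * f1[["meta:total_posts"]])

  # degenerate window is flagged, topic loadings all zero
  fe <- featurize(tokenized_window(posts[0, ], "recent"), res)
  expect_true(attr(fe, "degenerate"))
  expect_true(all(fe[grep("^topic:", names(fe))] == 0))
})

test_that("optional n-gram block uses unigram denominators", {
  res <- tiny_resources()
  cfg <- pipeline_config(include_ngrams = TRUE)
  posts <- make_posts("p1", c("2014-01-01 10:00:00", "2014-01-01 11:00:00"),
                      c("a b", "b"))
  f <- featurize(tokenized_window(posts), res, cfg)
  expect_equal(f[["ngram:a_b"]], 1 / 3)   # 1 bigram over 3 unigram tokens
  expect_equal(f[["ngram:b"]], 2 / 3)
  expect_false("ngram:b_b" %in% names(f))  # never across post boundary
})
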