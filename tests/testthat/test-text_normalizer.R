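fx <- generate_fixtures()

test_that("strip_structure separates mentions, hashtags, URLs and specials", {
  s <- strip_structure("ask @ibddoctor about #IBD http://x.y")
  expect_equal(s$text, "ask about IBD")
  expect_equal(s$hashtags, "IBD")
  expect_equal(s$mentions, "ibddoctor")
  expect_equal(s$urls, "http://x.y")

  expect_equal(strip_structure(""),
               list(text = "", hashtags = character(), mentions = character(),
                    urls = character()))

  s2 <- strip_structure("pain & cramps (bad)")
  expect_equal(s2$text, "pain cramps bad")
  expect_equal(s2$hashtags, character())
  expect_equal(s2$mentions, character())
  expect_equal(s2$urls, character())
})

test_that("split_hashtag splits at case and digit boundaries only", {
  expect_equal(split_hashtag("InflammatoryBowelDisease"),
               c("Inflammatory", "Bowel", "Disease"))
  expect_equal(split_hashtag("ibd"), "ibd")
  expect_equal(split_hashtag("gutHealth2018"), c("gut", "Health", "2018"))
  # concatenation invariant on arbitrary tags
  for (tag in c("IBDAwareness", "glutenfree", "Type2Diabetes", "a1b2C3")) {
    expect_equal(paste(split_hashtag(tag), collapse = ""), tag)
  }
})

test_that("squeeze_repeats reduces 3+ runs to exactly 2 and never lengthens", {
  expect_equal(squeeze_repeats("haaaapppyy"), "haappyy")
  expect_equal(squeeze_repeats("happy"), "happy")
  expect_equal(squeeze_repeats("nooooo"), "noo")
  set.seed(42)
  for (i in 1:200) {
    x <- paste(sample(letters[1:3], sample(0:12, 1), replace = TRUE),
               collapse = "")
    y <- squeeze_repeats(x)
    expect_lte(nchar(y), nchar(x))
    expect_false(grepl("(.)\\1{2}", y))
  }
})

test_that("normalized_levenshtein matches the DP oracle on random pairs", {
  expect_equal(normalized_levenshtein("kitten", "sitting"), 1 - 3 / 7)
  expect_equal(normalized_levenshtein("colitis", "colitis"), 1)
  expect_equal(normalized_levenshtein("a", ""), 0)
  expect_equal(normalized_levenshtein("", ""), 1)
  set.seed(1)
  for (i in 1:1000) {
    a <- paste(sample(letters[1:5], sample(0:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(letters[1:5], sample(0:12, 1), replace = TRUE),
               collapse = "")
    expected <- if (nchar(a) == 0 && nchar(b) == 0) 1 else {
      1 - oracle_edit_distance(a, b) / max(nchar(a), nchar(b))
    }
    expect_equal(normalized_levenshtein(a, b), expected)
    expect_equal(normalized_levenshtein(a, b), normalized_levenshtein(b, a))
  }
})

test_that("correct_spelling picks the most similar suggestion", {
  sugg <- function(tok) c("colitis", "colitides")
  expect_equal(correct_spelling("colitus", c("pain"), sugg), "colitis")
  expect_equal(correct_spelling("pain", c("pain")), "pain")
  expect_equal(correct_spelling("zzzqqq", c("pain")), "zzzqqq")
  # tie breaks to the lexicographically smallest suggestion
  expect_equal(correct_spelling("abx", c("x"), function(t) c("abz", "aby")),
               "aby")
})

test_that("expand_abbreviations is a case-insensitive multi-token expansion", {
  abb <- fx$abbreviations
  expect_equal(expand_abbreviations("SBBOS", abb),
               c("small", "bowel", "bacterial", "overgrowth", "syndrome"))
  expect_equal(expand_abbreviations("hello", abb), "hello")
  expect_equal(expand_abbreviations("ibs", abb),
               c("irritable", "bowel", "syndrome"))
})

test_that("n-gram construction follows the counting identity", {
  clean <- normalize_tweets(
    tibble::tibble(id = "t1", text = "probiotic helps gut flora balance"),
    spelling = c(fx$spelling, "helps", "flora", "balance"),
    abbreviations = fx$abbreviations
  )
  toks <- clean$tokens[[1]]
  t_len <- nrow(toks)
  expect_equal(t_len, 5) # no stop words in the sentence
  expect_equal(nrow(clean$ngrams[[1]]), t_len + (t_len - 1) + (t_len - 2))

  # all-stop-word text degenerates to nothing
  clean0 <- normalize_tweets(
    tibble::tibble(id = "t2", text = "the and of it"),
    spelling = fx$spelling, abbreviations = fx$abbreviations
  )
  expect_equal(nrow(clean0$tokens[[1]]), 0)
  expect_equal(nrow(clean0$ngrams[[1]]), 0)

  clean3 <- normalize_tweets(
    tibble::tibble(id = "t3", text = "inflammatory bowel disease"),
    spelling = fx$spelling, abbreviations = fx$abbreviations
  )
  expect_true("inflammatory bowel disease" %in% clean3$ngrams[[1]]$ngram)
})

test_that("n-grams are contiguous token subsequences", {
  cfg <- synthetic_config(n_tweets = 40, n_users = 20, seed = 13)
  corp <- generate_corpus(cfg)
  clean <- normalize_tweets(ingest_corpus(corp$tweets)$tweets,
                            fx$spelling, fx$abbreviations)
  for (i in seq_len(nrow(clean))) {
    toks <- clean$tokens[[i]]$surface
    ng <- clean$ngrams[[i]]
    for (j in seq_len(nrow(ng))) {
      span <- toks[(ng$start[j] + 1):(ng$start[j] + ng$n[j])]
      expect_equal(paste(span, collapse = " "), ng$ngram[j])
    }
    expect_false(any(toks %in% default_stopwords()))
    expect_false(grepl("[#@]", clean$clean_text[i]))
  }
})

test_that("full normalization is idempotent", {
  cfg <- synthetic_config(n_tweets = 80, n_users = 30, seed = 21)
  corp <- generate_corpus(cfg)
  clean1 <- normalize_tweets(ingest_corpus(corp$tweets)$tweets,
                             fx$spelling, fx$abbreviations)
  clean2 <- normalize_tweets(
    tibble::tibble(id = clean1$id, text = clean1$clean_text),
    fx$spelling, fx$abbreviations
  )
  expect_equal(clean2$clean_text, clean1$clean_text)
  expect_equal(clean2$ngrams, clean1$ngrams)
})

test_that("planted misspellings are corrected back to their originals", {
  cfg <- synthetic_config(n_tweets = 300, n_users = 50, misspell_rate = 0.5,
                          seed = 31)
  corp <- generate_corpus(cfg)
  tweets <- ingest_corpus(corp$tweets)$tweets
  clean <- normalize_tweets(tweets, fx$spelling, fx$abbreviations)
  miss <- tidyr::unnest(corp$truth$tweets[, c("id", "misspellings")],
                        "misspellings")
  miss <- miss[miss$id %in% tweets$id, ]
  expect_gt(nrow(miss), 30)
  recovered <- vapply(seq_len(nrow(miss)), function(i) {
    toks <- clean$tokens[[match(miss$id[i], clean$id)]]$surface
    miss$original[i] %in% toks
  }, logical(1))
  # originals are in the dictionary and the nearest suggestion by design
  expect_gt(mean(recovered), 0.95)
})
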