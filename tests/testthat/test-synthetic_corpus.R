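test_that("identical config and seed give byte-identical JSONL output", {
  cfg <- synthetic_config(n_tweets = 100, n_users = 40, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(generate_corpus(cfg), f1)
  write_corpus_jsonl(generate_corpus(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
})

test_that("JSONL round-trips through the reader", {
  cfg <- synthetic_config(n_tweets = 60, n_users = 30, seed = 3)
  corp <- generate_corpus(cfg)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, f)
  back <- read_corpus_jsonl(f)
  expect_equal(nrow(back$tweets), nrow(corp$tweets))
  expect_equal(back$tweets$id, corp$tweets$id)
  expect_equal(back$tweets$text, corp$tweets$text)
  expect_equal(back$tweets$created_at, corp$tweets$created_at)
  expect_equal(back$tweets$mentions, corp$tweets$mentions)
  # the JSONL schema embeds users inside tweet records, so only authors
  # survive a round trip
  expect_setequal(back$users$screen_name, unique(corp$tweets$screen_name))
})

test_that("non-English fraction falls in its binomial 99% interval", {
  # n = 1000, p = 0.1: the 99% binomial interval is ~[76, 125]; the looser
  # [60, 140] band makes a false alarm essentially impossible
  cfg <- synthetic_config(n_tweets = 1000, n_users = 200,
                          frac_non_english = 0.1, seed = 1)
  corp <- generate_corpus(cfg)
  n_non_en <- sum(corp$tweets$lang != "en")
  expect_gte(n_non_en, 60)
  expect_lte(n_non_en, 140)
})

test_that("zero mention rates give empty planted mention lists", {
  rates <- setNames(rep(0, 5), c("Disease", "Symptom", "Food and Diet",
                                 "Treatment", "Drug"))
  cfg <- synthetic_config(n_tweets = 50, n_users = 20,
                          mention_rate_per_category = rates, seed = 2)
  corp <- generate_corpus(cfg)
  expect_true(all(vapply(corp$truth$tweets$mentions, nrow, integer(1)) == 0))
})

test_that("invalid proportions are rejected", {
  expect_error(
    synthetic_config(user_type_mix = c(organization = 0.5, patient = 0.6,
                                       expert = 0, unknown = 0)),
    "sum to 1"
  )
  expect_error(synthetic_config(frac_non_english = 1.5), "rates")
  expect_error(
    synthetic_config(date_range = c("2018-08-31", "2018-02-01")),
    "date_range"
  )
})

test_that("fixtures plant the documented edge cases", {
  fx <- generate_fixtures()
  gaz <- fx$gazetteer
  # same name in two countries, twice: once tz-resolvable, once not
  dup <- gaz |> dplyr::count(name) |> dplyr::filter(n > 1)
  expect_true("guadalajara" %in% dup$name)
  expect_true("georgetown" %in% dup$name)
  gtown <- gaz[gaz$name == "georgetown", ]
  expect_equal(length(unique(gtown$time_zone)), 1)
  expect_equal(length(unique(gtown$country)), 2)
  # nested bigram/trigram pair per category
  lex <- fx$lexicon
  expect_true(all(c("bowel disease", "inflammatory bowel disease") %in% lex$term))
  for (cat in c("Disease", "Symptom", "Food and Diet", "Treatment", "Drug")) {
    terms <- lex$term[lex$category == cat]
    n_words <- lengths(strsplit(terms, " "))
    nested <- any(vapply(terms[n_words == 2], function(b) {
      any(grepl(b, terms[n_words == 3], fixed = TRUE))
    }, logical(1)))
    expect_true(nested, label = paste("nested pair in", cat))
  }
  # cross-category duplicate present in the raw fixture
  expect_gte(sum(lex$term == "ginger"), 2)
  # abbreviation worked example
  abb <- fx$abbreviations
  expect_equal(abb$expansion[abb$abbreviation == "sbbos"],
               "small bowel bacterial overgrowth syndrome")
})

test_that("fixtures round-trip through TSV files", {
  fx <- generate_fixtures()
  dir <- withr::local_tempdir()
  write_fixtures(fx, dir)
  back <- read_fixtures(dir)
  expect_equal(back$gazetteer$name, fx$gazetteer$name)
  expect_equal(back$spelling, fx$spelling)
  expect_equal(back$lexicon$term, fx$lexicon$term)
  expect_equal(back$valence$score, fx$valence$score)
})

test_that("user-type and gender composition match the configured mix", {
  cfg <- synthetic_config(n_tweets = 10, n_users = 2000, seed = 5)
  corp <- generate_corpus(cfg)
  tu <- corp$truth$users
  types <- table(factor(tu$type, levels = names(cfg$user_type_mix)))
  p_type <- stats::chisq.test(types, p = cfg$user_type_mix)$p.value
  expect_gt(p_type, 0.01)
  ind <- tu[tu$type %in% c("patient", "expert"), ]
  genders <- table(factor(ind$gender, levels = names(cfg$gender_mix)))
  p_gender <- stats::chisq.test(genders, p = cfg$gender_mix)$p.value
  expect_gt(p_gender, 0.01)
})

test_that("event-window tweets carry inflated interaction counts", {
  cfg <- synthetic_config(n_tweets = 2000, n_users = 100, seed = 9)
  corp <- generate_corpus(cfg)
  tt <- corp$truth$tweets
  inter <- corp$tweets$retweet_count + corp$tweets$favorite_count
  expect_gt(mean(inter[tt$in_event_window]), 2 * mean(inter[!tt$in_event_window]))
})
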