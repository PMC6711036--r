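fx <- generate_fixtures()

test_that("share_percentage rounds half-up to two decimals", {
  expect_equal(share_percentage(11688, 32794), 35.64)
  expect_equal(share_percentage(7975, 13295), 59.98)
  expect_equal(share_percentage(0, 10), 0)
  expect_equal(share_percentage(1, 1), 100)
  expect_equal(share_percentage(1, 3), 33.33)
  # exact half rounds up, unlike base round()
  expect_equal(share_percentage(125, 1000), 12.5)
  expect_equal(share_percentage(1005, 100000), 1.01)
  expect_error(share_percentage(1, 0), "positive")
  expect_error(share_percentage(5, 4), "count")
})

test_that("uplift reproduces the event-window arithmetic", {
  expect_equal(uplift_percent(3314, 1902), 174L)
  expect_equal(uplift_percent(13585, 4130), 329L)
  expect_equal(uplift_percent(500, 500), 100L)
  rows <- tibble::tibble(month = c("2018-04", "2018-05", "2018-06", "2018-07"),
                         n_interactions = c(1902, 3314, 3314, 1902))
  expect_equal(event_uplift(rows, c("2018-05", "2018-06")), 174L)
  expect_error(event_uplift(rows, rows$month), "baseline")
  expect_error(event_uplift(rows, "2020-01"), "not found")
})

test_that("term-frequency rows sum interactions over mentioning tweets", {
  tweets <- tibble::tibble(
    id = c("t1", "t2", "t3", "t4"),
    retweet_count = c(1L, 0L, 4L, 9L),
    favorite_count = c(2L, 0L, 5L, 9L),
    hashtags = list("anxiety", character(), c("AnxietyDisorder", "IBD"),
                    character())
  )
  mentions <- tibble::tibble(
    tweet_id = c("t1", "t2", "t3", "t3"),
    term = c("anxiety disorder", "anxiety disorder", "anxiety disorder",
             "inflammatory bowel disease"),
    category = c("Disease", "Disease", "Disease", "Disease")
  )
  tf <- term_frequency_table(mentions, tweets, fx$abbreviations)
  row <- tf[tf$term == "anxiety disorder", ]
  expect_equal(row$n_tweets, 3L)
  expect_equal(row$n_favorites, 7L)
  expect_equal(row$n_retweets, 5L)
  # "#anxiety" and "#AnxietyDisorder" both count as variants
  expect_equal(row$n_hashtags, 2L)
  # "#IBD" expands through the abbreviation dictionary
  ibd <- tf[tf$term == "inflammatory bowel disease", ]
  expect_equal(ibd$n_hashtags, 1L)

  # duplicated mention records do not inflate counts
  tf2 <- term_frequency_table(dplyr::bind_rows(mentions, mentions[1, ]),
                              tweets, fx$abbreviations)
  expect_equal(tf2[tf2$term == "anxiety disorder", ]$n_tweets, 3L)
  # and tweet order does not matter
  tf3 <- term_frequency_table(mentions[4:1, ], tweets[4:1, ],
                              fx$abbreviations)
  expect_equal(dplyr::arrange(tf3, term), dplyr::arrange(tf, term))
})

test_that("category sentiment table reproduces counts and percentages", {
  mentions <- tibble::tibble(
    tweet_id = c("t1", "t2", "t3", "t3"),
    term = c("diarrhea", "diarrhea", "diarrhea", "gluten"),
    category = c("Disease", "Disease", "Disease", "Food and Diet")
  )
  sentiments <- tibble::tibble(
    tweet_id = c("t1", "t2", "t3"),
    label = c("negative", "neutral", "positive")
  )
  tab <- sentiment_by_category(mentions, sentiments)
  dis <- tab[tab$meta_category == "Disease", ]
  expect_equal(c(dis$n_negative, dis$n_neutral, dis$n_positive), c(1L, 1L, 1L))
  expect_equal(c(dis$pct_negative, dis$pct_neutral, dis$pct_positive),
               c(33.33, 33.33, 33.33))
  # the multi-category tweet counts once in each category it touches
  expect_equal(tab[tab$meta_category == "Food and Diet", ]$n_total, 1L)
  expect_equal(nrow(tab), 2) # empty categories omitted

  # percentages per row are reproducible and sum to ~100
  cfg <- synthetic_config(n_tweets = 300, n_users = 80, seed = 71)
  res <- run_pipeline(cfg)
  t2 <- res$tables$sentiment_by_category
  expect_equal(t2$pct_negative, share_percentage(t2$n_negative, t2$n_total))
  expect_equal(t2$n_total, t2$n_negative + t2$n_neutral + t2$n_positive)
  expect_true(all(abs(t2$pct_negative + t2$pct_neutral + t2$pct_positive - 100)
                  <= 0.02))
})

test_that("account filtering restricts the category table to patient tweets", {
  cfg <- synthetic_config(n_tweets = 300, n_users = 80, seed = 73)
  res <- run_pipeline(cfg)
  pat_users <- res$profiles$screen_name[res$profiles$account_type == "patient"]
  pat_ids <- res$tweets$id[res$tweets$screen_name %in% pat_users]
  tab <- sentiment_by_category(res$mentions, res$sentiments, res$tweets,
                               res$profiles, "patient")
  by_hand <- res$mentions |>
    dplyr::filter(.data$tweet_id %in% pat_ids) |>
    dplyr::distinct(.data$tweet_id, .data$category) |>
    dplyr::count(.data$category)
  expect_equal(sum(tab$n_total), sum(by_hand$n))
})

test_that("monthly buckets are contiguous and uplift needs a baseline", {
  tweets <- tibble::tibble(
    id = c("a", "b", "c"),
    created_at = as.POSIXct(c("2018-02-10", "2018-02-20", "2018-05-01"),
                            tz = "UTC"),
    retweet_count = c(1L, 2L, 30L),
    favorite_count = c(0L, 1L, 10L)
  )
  rows <- monthly_activity(tweets)
  expect_equal(rows$month,
               c("2018-02", "2018-03", "2018-04", "2018-05"))
  expect_equal(rows$n_tweets, c(2L, 0L, 0L, 1L))
  expect_equal(rows$n_interactions, c(4L, 0L, 0L, 40L))
})

test_that("URL table groups per URL and poster type, sorted by summed counts", {
  tweets <- tibble::tibble(
    id = paste0("t", 1:4),
    screen_name = c("org1", "org1", "pat1", "zzz"),
    retweet_count = c(31L, 0L, 5L, 1L),
    favorite_count = c(50L, 0L, 2L, 1L),
    urls = list("https://a.example.org/x", "https://a.example.org/x",
                "https://b.example.com/y", "https://b.example.com/y")
  )
  profiles <- tibble::tibble(
    screen_name = c("org1", "pat1", "zzz"),
    account_type = c("organization", "patient", "unknown")
  )
  tab <- url_table(tweets, profiles)
  org_row <- tab[tab$poster_type == "organization", ]
  expect_equal(org_row$n_tweets + org_row$n_retweets + org_row$n_favorites, 83L)
  expect_equal(org_row$domain, "a.example.org")
  expect_setequal(tab$poster_type, c("organization", "patient", "other"))
  expect_equal(nrow(url_table(tweets[0, ], profiles)), 0)
})

test_that("geography counts cover exactly the resolved users", {
  profiles <- tibble::tibble(
    screen_name = paste0("u", 1:5),
    country = c("United States", "United States", "Spain", NA, "United States"),
    continent = c("America", "America", "Europe", NA, "America")
  )
  geo <- geo_distribution(profiles)
  expect_equal(geo$by_country$n_users[geo$by_country$country == "United States"], 3L)
  expect_equal(sum(geo$by_country$n_users), 4L)
  expect_equal(sum(geo$by_continent$n_users), 4L)
})
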