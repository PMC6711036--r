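make_tweets <- function(df) {
  defaults <- tibble::tibble(
    id = paste0("t", seq_len(nrow(df))),
    screen_name = "a", text = "", lang = "en",
    created_at = as.POSIXct("2018-05-01", tz = "UTC"),
    retweet_count = 0L, favorite_count = 0L,
    reply_to = NA_character_, retweet_of = NA_character_,
    hashtags = list(character()), mentions = list(character()),
    urls = list(character())
  )
  for (nm in names(df)) defaults[[nm]] <- df[[nm]]
  defaults
}

test_that("interaction edges sum mentions, retweets and replies", {
  tw <- make_tweets(tibble::tibble(
    screen_name = c("A", "A", "A"),
    mentions = list(c("B"), c("B"), character()),
    retweet_of = c(NA, NA, "B")
  ))
  g <- build_interaction_graph(tw)
  e <- tidy(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 3)
  expect_equal(e$from, "A")
  expect_equal(e$to, "B")

  # replies count as mentions by default, not when disabled
  tw2 <- make_tweets(tibble::tibble(screen_name = "A",
                                    reply_to = "B"))
  expect_equal(tidy(build_interaction_graph(tw2))$weight, 1)
  expect_equal(igraph::ecount(build_interaction_graph(tw2, include_replies = FALSE)), 0)

  # no interactions at all -> empty edge set
  expect_equal(igraph::ecount(build_interaction_graph(make_tweets(tibble::tibble(screen_name = "A")))), 0)
})

test_that("a hub mentioned by k users has in-degree k", {
  k <- 6
  tw <- make_tweets(tibble::tibble(
    screen_name = paste0("u", seq_len(k)),
    mentions = rep(list("hub"), k)
  ))
  g <- build_interaction_graph(tw)
  m <- graph_metrics(g)
  expect_equal(m$in_degree[m$name == "hub"], k)
  expect_equal(sum(m$in_degree), sum(m$out_degree))
})

test_that("in/out-degree totals equal the interaction count", {
  cfg <- synthetic_config(n_tweets = 300, n_users = 60, seed = 51)
  corp <- generate_corpus(cfg)
  tweets <- ingest_corpus(corp$tweets)$tweets
  g <- build_interaction_graph(tweets)
  n_inter <- sum(lengths(tweets$mentions)) +
    sum(!is.na(tweets$reply_to)) + sum(!is.na(tweets$retweet_of))
  e <- tidy(g)
  expect_equal(sum(e$weight), n_inter)
  m <- graph_metrics(g)
  expect_equal(sum(m$in_degree), sum(m$out_degree))
})

test_that("co-occurrence enumerates unordered pairs with majority sentiment", {
  mentions <- tibble::tibble(
    tweet_id = c("t1", "t1", "t1", "t2"),
    term = c("cannabis", "pain", "diarrhea", "pain")
  )
  sentiments <- tibble::tibble(tweet_id = c("t1", "t2"),
                               label = c("negative", "positive"))
  g <- build_cooccurrence_graph(mentions, sentiments)
  e <- tidy(g)
  expect_equal(nrow(e), 3) # C(3, 2)
  expect_true(all(e$weight == 1))
  expect_true(all(e$sentiment_majority == "negative"))

  # single term, no edges
  g1 <- build_cooccurrence_graph(tibble::tibble(tweet_id = "t", term = "x"))
  expect_equal(igraph::ecount(g1), 0)

  # 2 negative + 1 positive -> negative majority; 1-1 tie -> neutral
  m2 <- tibble::tibble(tweet_id = rep(c("t1", "t2", "t3", "t4"), each = 2),
                       term = rep(c("a", "b"), 4))
  s2 <- tibble::tibble(tweet_id = paste0("t", 1:4),
                       label = c("negative", "negative", "positive", "positive"))
  e2 <- tidy(build_cooccurrence_graph(m2[1:6, ], s2))
  expect_equal(e2$sentiment_majority, "negative")
  e3 <- tidy(build_cooccurrence_graph(m2[c(1:2, 5:6), ], s2))
  expect_equal(e3$sentiment_majority, "neutral")
})

test_that("total co-occurrence weight is the sum of per-tweet pair counts", {
  cfg <- synthetic_config(n_tweets = 300, n_users = 60, seed = 53)
  res <- run_pipeline(cfg)
  e <- tidy(res$cooccurrence_graph)
  per_tweet <- res$mentions |>
    dplyr::distinct(.data$tweet_id, .data$term) |>
    dplyr::count(.data$tweet_id)
  expect_equal(sum(e$weight), sum(choose(per_tweet$n, 2)))
})

test_that("closed-form metrics on small canonical graphs", {
  # path a-b-c: b mediates the single pair; no triangles
  path <- igraph::graph_from_literal(a - b, b - c)
  mp <- graph_metrics(path)
  expect_equal(mp$betweenness[mp$name == "b"], 1)
  expect_equal(mp$betweenness[mp$name != "b"], c(0, 0))
  expect_equal(mp$clustering, c(0, 0, 0))
  expect_equal(mp$closeness[mp$name == "b"], 2 / 2)
  expect_equal(mp$closeness[mp$name == "a"], 2 / 3)

  # triangle: full clustering, unit path length
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  mt <- graph_metrics(tri)
  expect_equal(mt$clustering, c(1, 1, 1))
  expect_equal(graph_summary(tri)$characteristic_path_length, 1)

  # star K1,4: center has degree centrality 1
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:5)
  ms <- graph_metrics(star)
  expect_equal(ms$degree_centrality[1], 1)

  # degenerate single node
  single <- igraph::make_empty_graph(n = 1, directed = FALSE)
  igraph::V(single)$name <- "only"
  m1 <- graph_metrics(single)
  expect_equal(m1$betweenness, 0)
  expect_equal(m1$closeness, 0)
  expect_equal(m1$degree_centrality, 0)
})

test_that("metrics match the brute-force oracle on random graphs", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    directed <- rep %% 2 == 0
    adj <- matrix(rbinom(n * n, 1, 0.25), n, n)
    diag(adj) <- 0
    g <- graph_from_adj(adj, directed)
    got <- graph_metrics(g)
    want <- oracle_graph_metrics(adj, directed)
    expect_equal(got$in_degree, want$in_degree)
    expect_equal(got$out_degree, want$out_degree)
    expect_equal(got$degree_centrality, want$degree_centrality)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-9)
    gs <- graph_summary(g)
    expect_equal(gs$characteristic_path_length,
                 want$characteristic_path_length, tolerance = 1e-9)
    expect_equal(gs$average_neighbors, want$average_neighbors)
  }
})

test_that("communities are components strictly larger than min_size", {
  g <- igraph::graph_from_literal(a - b, b - c, c - d, d - e, e - f, f - g,
                          x - y, y - z)
  comm <- extract_communities(g, min_size = 5)
  expect_equal(nrow(comm), 1)
  expect_equal(comm$size, 7)
  expect_setequal(comm$members[[1]], c("a", "b", "c", "d", "e", "f", "g"))

  expect_equal(nrow(extract_communities(igraph::make_empty_graph(0))), 0)

  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- paste0("n", 1:10)
  c10 <- extract_communities(k10)
  expect_equal(c10$size, 10)
})

test_that("graph tidiers expose edges and graph-level summaries", {
  cfg <- synthetic_config(n_tweets = 100, n_users = 30, seed = 67)
  res <- run_pipeline(cfg)
  e <- tidy(res$interaction_graph)
  expect_true(all(c("from", "to", "weight") %in% names(e)))
  gl <- glance(res$interaction_graph)
  expect_equal(gl$n_edges, nrow(e))
  expect_true(all(c("characteristic_path_length", "average_neighbors") %in%
                    names(gl)))
})
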