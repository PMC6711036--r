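# End-to-end orchestration: ingest -> normalize -> profile -> recognize ->
# score -> graphs -> summary tables. Deterministic given a config (seed
# included), so two runs write byte-identical tables.

#' Ingest a corpus: deduplicate and keep English tweets
#'
#' @param tweets tweet tibble (e.g. from [read_corpus_jsonl()]).
#' @return list with `tweets` (unique, English) and `n_removed`
#'   (non-English or duplicate records dropped).
#' @export
ingest_corpus <- function(tweets) {
  n0 <- nrow(tweets)
  out <- tweets |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::filter(.data$lang == "en")
  list(tweets = out, n_removed = n0 - nrow(out))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a corpus, then runs every stage: ingest,
#' normalization, user profiling, entity recognition, sentiment scoring,
#' interaction and co-occurrence graphs, and the summary tables. With an
#' output directory, all tables are written as CSV (plus a JSON run
#' manifest), deterministically.
#'
#' @param config a [synthetic_config()]; ignored when `corpus` is given.
#' @param corpus optional pre-built corpus list (`tweets`, `users`) — e.g.
#'   from [read_corpus_jsonl()]; fixtures must then be supplied too.
#' @param fixtures fixture list; defaults to [generate_fixtures()].
#' @param out_dir optional output directory for CSV tables.
#' @param account_filter account type for the category-sentiment table
#'   (default `"patient"`).
#' @return list with all intermediate and final artifacts: `tweets`,
#'   `users`, `clean`, `profiles`, `lexicon`, `mentions`, `sentiments`,
#'   `interaction_graph`, `cooccurrence_graph`, `tables` (named list),
#'   and `truth` when the corpus was generated.
#' @export
run_pipeline <- function(config = synthetic_config(), corpus = NULL,
                         fixtures = NULL, out_dir = NULL,
                         account_filter = "patient") {
  if (is.null(corpus)) {
    fixtures <- fixtures %||% generate_fixtures(config)
    corpus <- generate_corpus(config, fixtures)
  } else {
    stopifnot(!is.null(fixtures))
  }
  ing <- ingest_corpus(corpus$tweets)
  tweets <- ing$tweets

  clean <- normalize_tweets(tweets, fixtures$spelling, fixtures$abbreviations,
                            fixtures$stopwords %||% default_stopwords())
  profiles <- profile_users(corpus$users, fixtures)
  lexicon <- build_lexicon(fixtures$lexicon)
  mentions <- recognize_corpus(clean, lexicon)
  sentiments <- score_corpus(tweets, fixtures$valence)

  ig <- build_interaction_graph(tweets, profiles)
  cg <- build_cooccurrence_graph(mentions, sentiments)

  monthly <- monthly_activity(tweets)
  tables <- list(
    term_frequency = term_frequency_table(mentions, tweets,
                                          fixtures$abbreviations),
    sentiment_by_category = sentiment_by_category(
      mentions, sentiments, tweets, profiles, account_filter
    ),
    monthly_activity = monthly,
    url_table = url_table(tweets, profiles),
    geo_by_country = geo_distribution(profiles)$by_country,
    geo_by_continent = geo_distribution(profiles)$by_continent
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      write_table_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("bowelwatch")),
      seed = config$seed,
      n_tweets_in = nrow(corpus$tweets),
      n_tweets_analyzed = nrow(tweets),
      n_removed = ing$n_removed
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(
    tweets = tweets,
    users = corpus$users,
    truth = corpus$truth,
    fixtures = fixtures,
    clean = clean,
    profiles = profiles,
    lexicon = lexicon,
    mentions = mentions,
    sentiments = sentiments,
    interaction_graph = ig,
    cooccurrence_graph = cg,
    tables = tables,
    n_removed = ing$n_removed
  )
}
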