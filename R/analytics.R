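# Results-table analytics: term frequency (with hashtag variant counting),
# sentiment by semantic category, monthly activity and event uplift, URL
# and geography summaries. All percentages go through share_percentage()
# (half-up, two decimals); uplifts round half-up to integers.

#' Term-frequency table
#'
#' One row per recognized term: the number of tweets mentioning it, the
#' summed favorite and retweet counts of those tweets, and how often the
#' term (or a variant) was used in hashtags. A hashtag matches a term when
#' its split, normalized, lemmatized form equals the term, is a word-prefix
#' of it (e.g. `#anxiety` for *anxiety disorder*), or expands to it through
#' the abbreviation dictionary (e.g. `#IBD`).
#'
#' @param mentions mention tibble from [recognize_corpus()].
#' @param tweets tweet tibble (for interaction counts and hashtags).
#' @param abbreviations optional abbreviation dictionary for hashtag
#'   variants.
#' @return tibble sorted by `n_tweets` descending: `term`,
#'   `meta_category`, `n_tweets`, `n_favorites`, `n_retweets`,
#'   `n_hashtags`.
#' @export
term_frequency_table <- function(mentions, tweets, abbreviations = NULL) {
  mentions <- dplyr::distinct(mentions, .data$tweet_id, .data$term,
                              .keep_all = TRUE)
  base <- mentions |>
    dplyr::left_join(
      tweets |>
        dplyr::select("id", "retweet_count", "favorite_count") |>
        dplyr::rename(tweet_id = "id"),
      by = "tweet_id"
    ) |>
    dplyr::group_by(.data$term, meta_category = .data$category) |>
    dplyr::summarise(
      n_tweets = dplyr::n_distinct(.data$tweet_id),
      n_favorites = sum(.data$favorite_count, na.rm = TRUE),
      n_retweets = sum(.data$retweet_count, na.rm = TRUE),
      .groups = "drop"
    )

  # hashtag variant counting over the whole corpus
  all_tags <- unlist(tweets$hashtags)
  tag_phrases <- vapply(all_tags, function(tag) {
    words <- tolower(split_hashtag(tag))
    if (!is.null(abbreviations) && length(words) == 1) {
      hit <- match(words, tolower(abbreviations$abbreviation))
      if (!is.na(hit)) {
        words <- strsplit(abbreviations$expansion[hit], " ", fixed = TRUE)[[1]]
      }
    }
    paste(vapply(words, lemmatize_token, character(1)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)

  n_hashtags <- vapply(base$term, function(term) {
    tw <- strsplit(term, " ", fixed = TRUE)[[1]]
    tw <- vapply(tw, lemmatize_token, character(1), USE.NAMES = FALSE)
    sum(vapply(tag_phrases, function(ph) {
      pw <- strsplit(ph, " ", fixed = TRUE)[[1]]
      k <- min(length(pw), length(tw))
      identical(pw[seq_len(k)], tw[seq_len(k)])
    }, logical(1)))
  }, numeric(1), USE.NAMES = FALSE)

  base |>
    dplyr::mutate(n_hashtags = as.integer(n_hashtags)) |>
    dplyr::arrange(dplyr::desc(.data$n_tweets), .data$term)
}

#' Sentiment distribution by semantic category
#'
#' A tweet contributes to a category when it contains at least one mention
#' of that category (a tweet may count in several categories, once per
#' category). Optionally restricted to tweets posted by a given account
#' type (e.g. patients). Percentages are recomputed from the counts via
#' [share_percentage()].
#'
#' @param mentions mention tibble from [recognize_corpus()].
#' @param sentiments sentiment tibble from [score_corpus()].
#' @param tweets optional tweet tibble (needed for the account filter).
#' @param profiles optional profile tibble (needed for the account filter).
#' @param account_filter optional account type (e.g. `"patient"`).
#' @return tibble: `meta_category`, `n_negative`, `n_neutral`,
#'   `n_positive`, `n_total`, `pct_negative`, `pct_neutral`,
#'   `pct_positive` (empty categories omitted).
#' @export
sentiment_by_category <- function(mentions, sentiments, tweets = NULL,
                                  profiles = NULL, account_filter = NULL) {
  tagged <- dplyr::distinct(mentions, .data$tweet_id, .data$category)
  if (!is.null(account_filter)) {
    stopifnot(!is.null(tweets), !is.null(profiles))
    keep_users <- profiles$screen_name[profiles$account_type == account_filter]
    keep_ids <- tweets$id[tweets$screen_name %in% keep_users]
    tagged <- dplyr::filter(tagged, .data$tweet_id %in% keep_ids)
  }
  tagged |>
    dplyr::left_join(sentiments[, c("tweet_id", "label")], by = "tweet_id") |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::count(meta_category = .data$category, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L) |>
    add_missing_label_cols() |>
    dplyr::mutate(
      n_total = .data$negative + .data$neutral + .data$positive,
      pct_negative = share_percentage(.data$negative, .data$n_total),
      pct_neutral = share_percentage(.data$neutral, .data$n_total),
      pct_positive = share_percentage(.data$positive, .data$n_total)
    ) |>
    dplyr::rename(n_negative = "negative", n_neutral = "neutral",
                  n_positive = "positive") |>
    dplyr::mutate(meta_category = factor(.data$meta_category,
                                         levels = META_CATEGORIES)) |>
    dplyr::arrange(.data$meta_category) |>
    dplyr::mutate(meta_category = as.character(.data$meta_category)) |>
    dplyr::select("meta_category", "n_negative", "n_neutral", "n_positive",
                  "n_total", "pct_negative", "pct_neutral", "pct_positive")
}

add_missing_label_cols <- function(df) {
  for (lab in c("negative", "neutral", "positive")) {
    if (!lab %in% names(df)) df[[lab]] <- 0L
  }
  df
}

#' Monthly posting and interaction activity
#'
#' Buckets tweets by calendar month (UTC) over the full corpus date range
#' (empty months appear with zero counts); interactions are retweets plus
#' favorites.
#'
#' @param tweets tweet tibble.
#' @return tibble: `month` (`"YYYY-MM"`), `n_tweets`, `n_interactions`.
#' @export
monthly_activity <- function(tweets) {
  stopifnot(nrow(tweets) > 0)
  month <- format(tweets$created_at, "%Y-%m", tz = "UTC")
  rng <- range(tweets$created_at)
  all_months <- format(
    seq(as.Date(format(rng[1], "%Y-%m-01", tz = "UTC")),
        as.Date(format(rng[2], "%Y-%m-01", tz = "UTC")), by = "month"),
    "%Y-%m"
  )
  tibble::tibble(
    month = month,
    interactions = tweets$retweet_count + tweets$favorite_count
  ) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(n_tweets = dplyr::n(),
                     n_interactions = sum(.data$interactions),
                     .groups = "drop") |>
    dplyr::right_join(tibble::tibble(month = all_months), by = "month") |>
    dplyr::mutate(
      n_tweets = tidyr::replace_na(.data$n_tweets, 0L),
      n_interactions = tidyr::replace_na(.data$n_interactions, 0L)
    ) |>
    dplyr::arrange(.data$month)
}

#' Event uplift of interaction volume
#'
#' The ratio (x100, rounded half-up to an integer) of the mean monthly
#' value inside an event window to the mean over the remaining months —
#' e.g. mean retweets of 3314 in the event months against 1902 outside
#' gives an uplift of 174.
#'
#' @param rows monthly activity tibble (from [monthly_activity()] or any
#'   tibble with a `month` column and the `value` column).
#' @param window_months character vector of `"YYYY-MM"` months in the
#'   event window (must be a strict subset of the covered months).
#' @param value name of the numeric column to compare (default
#'   `"n_interactions"`).
#' @return integer uplift percentage.
#' @export
event_uplift <- function(rows, window_months, value = "n_interactions") {
  stopifnot(value %in% names(rows))
  in_win <- rows$month %in% window_months
  if (!any(in_win)) {
    stop("window_months not found in `rows`", call. = FALSE)
  }
  if (all(in_win)) {
    stop("event window leaves no baseline months", call. = FALSE)
  }
  uplift_percent(mean(rows[[value]][in_win]), mean(rows[[value]][!in_win]))
}

#' Uplift percentage from two means
#'
#' `100 * window_mean / baseline_mean`, rounded half-up to an integer.
#'
#' @param window_mean mean value inside the event window.
#' @param baseline_mean mean value outside it (positive).
#' @return integer percentage.
#' @examples
#' uplift_percent(3314, 1902)
#' @export
uplift_percent <- function(window_mean, baseline_mean) {
  stopifnot(baseline_mean > 0)
  as.integer(round_half_up(100 * window_mean / baseline_mean, 0))
}

#' URL summary table
#'
#' Groups tweets by distinct URL and poster type (organization, patient,
#' other), counting tweets, retweets and favorites; rows sort by the sum
#' of the three counts, descending, within each poster type.
#'
#' @param tweets tweet tibble (list-column `urls`).
#' @param profiles profile tibble (for poster types).
#' @param top_k keep at most this many rows per poster type (default 10).
#' @param domain_categories optional tibble `domain`, `category` mapping
#'   URL domains to a free-text category (default `"uncategorized"`).
#' @return tibble: `url`, `domain`, `category`, `poster_type`, `n_tweets`,
#'   `n_retweets`, `n_favorites`.
#' @export
url_table <- function(tweets, profiles, top_k = 10, domain_categories = NULL) {
  unnested <- tweets |>
    dplyr::select("id", "screen_name", "retweet_count", "favorite_count",
                  "urls") |>
    tidyr::unnest_longer("urls", values_to = "url") |>
    dplyr::filter(!is.na(.data$url), nzchar(.data$url))
  if (nrow(unnested) == 0) {
    return(tibble::tibble(
      url = character(), domain = character(), category = character(),
      poster_type = character(), n_tweets = integer(),
      n_retweets = integer(), n_favorites = integer()
    ))
  }
  type_of <- setNames(profiles$account_type, profiles$screen_name)
  unnested$poster_type <- dplyr::case_when(
    type_of[unnested$screen_name] == "organization" ~ "organization",
    type_of[unnested$screen_name] == "patient" ~ "patient",
    TRUE ~ "other"
  )
  out <- unnested |>
    dplyr::group_by(.data$url, .data$poster_type) |>
    dplyr::summarise(
      n_tweets = dplyr::n(),
      n_retweets = sum(.data$retweet_count),
      n_favorites = sum(.data$favorite_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      domain = sub("^https?://([^/]+).*$", "\\1", .data$url),
      sort_key = .data$n_tweets + .data$n_retweets + .data$n_favorites
    )
  if (!is.null(domain_categories)) {
    out <- dplyr::left_join(out, domain_categories, by = "domain") |>
      dplyr::mutate(category = dplyr::coalesce(.data$category, "uncategorized"))
  } else {
    out$category <- "uncategorized"
  }
  out |>
    dplyr::group_by(.data$poster_type) |>
    dplyr::arrange(dplyr::desc(.data$sort_key), .data$url,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup() |>
    dplyr::select("url", "domain", "category", "poster_type", "n_tweets",
                  "n_retweets", "n_favorites")
}

#' Geographic distribution of resolved users
#'
#' @param profiles profile tibble from [profile_users()].
#' @return list with `by_country` and `by_continent` count tibbles
#'   (resolved users only; counts sum to the number of resolved users).
#' @export
geo_distribution <- function(profiles) {
  resolved <- dplyr::filter(profiles, !is.na(.data$country))
  list(
    by_country = dplyr::count(resolved, .data$country, .data$continent,
                              name = "n_users", sort = TRUE),
    by_continent = dplyr::count(resolved, .data$continent, name = "n_users",
                                sort = TRUE)
  )
}
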