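# Inverted longest-match entity recognition: the tweet's own 1-3-grams are
# used as lookup keys into the lexicon (there are far fewer n-grams in a
# tweet than terms in the lexicon). Longer n-grams win over shorter ones;
# among equal lengths the leftmost wins; consumed tokens are never re-used.

#' Recognize lexicon terms in a normalized tweet
#'
#' Candidate n-grams are tested longest-first (3, 2, 1) and, within a
#' length, left to right. A match consumes its token span, blocking any
#' shorter or overlapping match. For each window the surface form is tried
#' first, then the lemmatized form; spans containing tokens produced by
#' abbreviation expansion are recorded as abbreviation matches.
#'
#' @param tokens tibble of tweet tokens (`surface`, `lemma`, `from_abbrev`)
#'   as produced by [normalize_tweets()].
#' @param lexicon a [build_lexicon()] object.
#' @param allow_overlaps if `TRUE`, spans of different categories may
#'   overlap (off by default; all overlaps are forbidden).
#' @return tibble of mentions sorted by span start: `term`, `category`,
#'   `source`, `start`, `end` (half-open token span), `match_kind`.
#' @export
recognize <- function(tokens, lexicon, allow_overlaps = FALSE) {
  empty <- tibble::tibble(
    term = character(), category = character(), source = character(),
    start = integer(), end = integer(), match_kind = character()
  )
  t_len <- nrow(tokens)
  if (t_len == 0 || nrow(lexicon$entries) == 0) {
    return(empty)
  }
  entry_idx <- setNames(seq_len(nrow(lexicon$entries)), lexicon$entries$term)
  lemma_idx <- setNames(lexicon$lemma_index$term, lexicon$lemma_index$lemma_term)

  # per-category consumption only matters when overlaps are allowed:
  # a token may then serve mentions of different categories, but never two
  # of the same category (longest-match still wins within a category)
  consumed <- matrix(FALSE, nrow = t_len, ncol = length(META_CATEGORIES),
                     dimnames = list(NULL, META_CATEGORIES))
  out <- list()
  for (n in 3:1) {
    if (t_len < n) next
    for (s in 0:(t_len - n)) {
      span <- (s + 1):(s + n)
      if (!allow_overlaps && any(consumed[span, ])) next
      surface_key <- paste(tokens$surface[span], collapse = " ")
      lemma_key <- paste(tokens$lemma[span], collapse = " ")
      canon <- NULL
      kind <- NULL
      if (!is.na(entry_idx[surface_key])) {
        canon <- surface_key
        kind <- "exact"
      } else if (!is.na(entry_idx[lemma_key])) {
        canon <- lemma_key
        kind <- "lemma"
      } else if (!is.na(lemma_idx[lemma_key])) {
        canon <- unname(lemma_idx[lemma_key])
        kind <- "lemma"
      }
      if (is.null(canon)) next
      e <- lexicon$entries[entry_idx[canon], ]
      if (allow_overlaps && any(consumed[span, e$category])) next
      if (any(tokens$from_abbrev[span])) kind <- "abbreviation"
      out[[length(out) + 1]] <- tibble::tibble(
        term = e$term, category = e$category, source = e$source,
        start = as.integer(s), end = as.integer(s + n), match_kind = kind
      )
      consumed[span, e$category] <- TRUE
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Recognize entities across a normalized corpus
#'
#' Applies [recognize()] to every tweet and binds the results, keeping one
#' row per (tweet, term) pair — the counting convention of the summary
#' tables (a term counts once per tweet regardless of repeats).
#'
#' @param clean normalized corpus from [normalize_tweets()].
#' @param lexicon a [build_lexicon()] object.
#' @param dedupe keep one mention per (tweet, term) (default `TRUE`).
#' @return tibble: `tweet_id`, `term`, `category`, `source`, `start`,
#'   `end`, `match_kind`.
#' @export
recognize_corpus <- function(clean, lexicon, dedupe = TRUE) {
  res <- purrr::map2_dfr(clean$id, clean$tokens, function(id, toks) {
    m <- recognize(toks, lexicon)
    if (nrow(m) == 0) {
      return(NULL)
    }
    dplyr::mutate(m, tweet_id = id, .before = 1)
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(
      tweet_id = character(), term = character(), category = character(),
      source = character(), start = integer(), end = integer(),
      match_kind = character()
    ))
  }
  if (dedupe) {
    res <- dplyr::distinct(res, .data$tweet_id, .data$term, .keep_all = TRUE)
  }
  res
}
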