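# Tweet text normalization: the cleaning cascade applied before entity
# recognition. Order is fixed: structural stripping -> hashtag splitting ->
# repeated-letter squeezing -> spelling correction -> abbreviation expansion
# -> tokenization (stop-word removal, lemmatization, 1-3-gram construction).

# Characters carrying no content for the analysis; removed outright.
SPECIAL_CHARS_PATTERN <- "[&()*+<>\"“”]"

URL_PATTERN <- "(?i)\\b(?:https?://|www\\.)[^\\s]+"
MENTION_PATTERN <- "@(\\w+)"
HASHTAG_PATTERN <- "#(\\w+)"

# Unicode emoji blocks plus a small ASCII emoticon table; emoji survive
# cleaning as standalone tokens (the profiler uses them) but are dropped
# before n-gram construction.
EMOJI_PATTERN <- "[\\x{1F300}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}\\x{FE0F}]"
ASCII_EMOTICONS <- c(
  ":)", ":-)", ":(", ":-(", ":D", ":-D", ";)", ";-)", ":P", ":-P",
  ":/", ":-/", "<3", ":'(", "xD", "XD"
)

#' Strip structural elements from tweet text
#'
#' Extracts hashtags (losing their `#`), user mentions and URLs; mentions and
#' URLs are removed from the text while hashtag bodies remain in place.
#' Special characters (`&`, `(`, `)`, `*`, `+`, `<`, `>`, quotes) are deleted.
#'
#' @param text a single tweet text (UTF-8).
#' @return a list with elements `text`, `hashtags`, `mentions`, `urls`.
#' @examples
#' strip_structure("ask @ibddoctor about #IBD http://x.y")
#' @export
strip_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(list(text = "", hashtags = character(), mentions = character(), urls = character()))
  }
  urls <- stringr::str_extract_all(text, stringr::regex(URL_PATTERN))[[1]]
  out <- stringr::str_remove_all(text, stringr::regex(URL_PATTERN))
  mentions <- stringr::str_match_all(out, MENTION_PATTERN)[[1]][, 2]
  out <- stringr::str_remove_all(out, MENTION_PATTERN)
  hashtags <- stringr::str_match_all(out, HASHTAG_PATTERN)[[1]][, 2]
  # hashtag body stays in the text; only the marker goes
  out <- stringr::str_replace_all(out, HASHTAG_PATTERN, "\\1")
  out <- stringr::str_remove_all(out, SPECIAL_CHARS_PATTERN)
  out <- stringr::str_squish(out)
  list(
    text = out,
    hashtags = as.character(hashtags),
    mentions = as.character(mentions),
    urls = as.character(urls)
  )
}

#' Split a hashtag into words
#'
#' Splits at lower-to-upper case boundaries, acronym boundaries
#' (`IBDAwareness` -> `IBD`, `Awareness`) and letter/digit boundaries.
#' All-lowercase multiword tags are left unsplit (no dictionary
#' segmentation). Concatenating the result always reproduces the tag.
#'
#' @param tag hashtag body without the leading `#`.
#' @return character vector of words.
#' @examples
#' split_hashtag("InflammatoryBowelDisease")
#' split_hashtag("gutHealth2018")
#' @export
split_hashtag <- function(tag) {
  stopifnot(is.character(tag), length(tag) == 1)
  if (!nzchar(tag)) {
    return(character())
  }
  s <- gsub("([[:lower:]])([[:upper:]])", "\\1 \\2", tag)
  s <- gsub("([[:upper:]]+)([[:upper:]][[:lower:]])", "\\1 \\2", s)
  s <- gsub("([[:alpha:]])([0-9])", "\\1 \\2", s)
  s <- gsub("([0-9])([[:alpha:]])", "\\1 \\2", s)
  strsplit(s, " ", fixed = TRUE)[[1]]
}

#' Squeeze repeated characters
#'
#' Any run of three or more identical consecutive characters is reduced to
#' exactly two; shorter runs are untouched (`haaaapppyy` -> `haappyy`).
#'
#' @param x character vector.
#' @return character vector with runs squeezed.
#' @export
squeeze_repeats <- function(x) {
  gsub("(.)\\1{2,}", "\\1\\1", x, perl = TRUE)
}

#' Normalized Levenshtein similarity
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))` where `d` is the Levenshtein edit
#' distance. Equals 1 only for identical strings; two empty strings are
#' defined as similarity 1.
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric similarity in `[0, 1]`.
#' @examples
#' normalized_levenshtein("kitten", "sitting")
#' @export
normalized_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d <- diag(utils::adist(a, b))
  if (n == 1) d <- utils::adist(a, b)[1, 1]
  denom <- pmax(nchar(a), nchar(b))
  out <- ifelse(denom == 0, 1, 1 - d / denom)
  as.numeric(out)
}

#' Correct the spelling of a token
#'
#' Tokens already in the dictionary are returned unchanged. Otherwise the
#' suggester proposes candidates and the one with the highest normalized
#' Levenshtein similarity to the token wins; ties break to the
#' lexicographically smallest suggestion. With no suggestions the token
#' passes through unchanged.
#'
#' @param token a single lowercase token.
#' @param dictionary character vector of known words (lowercase).
#' @param suggester function `token -> character vector` of candidates;
#'   the default proposes dictionary words within edit distance 2.
#' @return the corrected (or original) token.
#' @export
correct_spelling <- function(token, dictionary, suggester = NULL) {
  stopifnot(is.character(token), length(token) == 1)
  if (token %in% dictionary) {
    return(token)
  }
  if (is.null(suggester)) {
    suggester <- function(tok) {
      d <- utils::adist(tok, dictionary)[1, ]
      dictionary[d <= 2]
    }
  }
  cands <- unique(suggester(token))
  if (length(cands) == 0) {
    return(token)
  }
  sims <- normalized_levenshtein(rep(token, length(cands)), cands)
  best <- cands[sims == max(sims)]
  sort(best)[1]
}

#' Expand an abbreviation
#'
#' Case-insensitive lookup in the abbreviation dictionary; on a hit the
#' expansion is returned split into its component tokens, otherwise the
#' token itself.
#'
#' @param token a single token.
#' @param abbreviations data frame with columns `abbreviation`, `expansion`.
#' @return character vector of one or more tokens.
#' @examples
#' abb <- data.frame(abbreviation = "sbbos",
#'                   expansion = "small bowel bacterial overgrowth syndrome")
#' expand_abbreviations("SBBOS", abb)
#' @export
expand_abbreviations <- function(token, abbreviations) {
  stopifnot(is.character(token), length(token) == 1)
  hit <- match(tolower(token), tolower(abbreviations$abbreviation))
  if (is.na(hit)) {
    return(token)
  }
  strsplit(abbreviations$expansion[hit], " ", fixed = TRUE)[[1]]
}

#' Default stop-word list
#'
#' A small English stop-word list (articles, prepositions, pronouns,
#' auxiliaries) removed before n-gram construction.
#'
#' @return character vector of stop words.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "the", "and", "or", "but", "if", "then", "so", "of", "to",
    "in", "on", "at", "by", "for", "with", "from", "about", "after",
    "before", "into", "over", "under", "again", "is", "am", "are", "was",
    "were", "be", "been", "being", "do", "does", "did", "have", "has",
    "had", "will", "would", "can", "could", "should", "it", "its", "this",
    "that", "these", "those", "there", "here", "i", "im", "i'm", "ive",
    "i've", "me", "my", "mine", "myself", "we", "our", "ours", "ourselves",
    "you", "your", "yours", "he", "him", "his", "she", "her", "hers",
    "they", "them", "their", "theirs", "what", "which", "who", "as",
    "not", "no", "too", "very", "just", "up", "down", "out", "all", "some"
  )
}

# Suffix-stripping lemmatizer stub: plural reduction only. A pluggable
# interface point; full morphological lemmatization is out of scope.
lemmatize_token <- function(token) {
  n <- nchar(token)
  if (n > 4 && endsWith(token, "ies")) {
    return(paste0(substr(token, 1, n - 3), "y"))
  }
  if (n > 3 && endsWith(token, "s") &&
      !endsWith(token, "ss") && !endsWith(token, "us") && !endsWith(token, "is")) {
    return(substr(token, 1, n - 1))
  }
  token
}

is_emoji_token <- function(token) {
  token %in% ASCII_EMOTICONS ||
    stringr::str_detect(token, stringr::regex(EMOJI_PATTERN))
}

# Full single-tweet normalization. Returns list(clean_text, tokens, ngrams,
# hashtags, mentions, urls); tokens is a tibble with surface/lemma/pos/
# from_abbrev, ngrams a tibble with ngram/n/start (half-open token spans
# over the kept-token sequence).
normalize_text <- function(text, spelling, abbreviations,
                           stopwords = default_stopwords(),
                           pos_tagger = NULL) {
  s <- strip_structure(text)
  txt <- s$text
  # replace each in-place hashtag body with its split words
  for (tag in s$hashtags) {
    words <- split_hashtag(tag)
    if (length(words) > 1) {
      txt <- stringr::str_replace(
        txt, stringr::fixed(tag), paste(words, collapse = " ")
      )
    }
  }
  txt <- squeeze_repeats(txt)
  # hyphens/underscores become spaces so n-grams align with the lexicon
  txt <- gsub("[-_]", " ", txt)
  raw <- strsplit(stringr::str_squish(txt), " ", fixed = TRUE)[[1]]
  raw <- raw[nzchar(raw)]

  surface <- character()
  from_abbrev <- logical()
  emoji <- logical()
  dict <- tolower(spelling)
  for (tok in raw) {
    if (is_emoji_token(tok)) {
      surface <- c(surface, tok)
      from_abbrev <- c(from_abbrev, FALSE)
      emoji <- c(emoji, TRUE)
      next
    }
    # strip edge punctuation (apostrophes kept inside words)
    tok <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tok)
    if (!nzchar(tok)) next
    low <- tolower(tok)
    if (grepl("^[[:alpha:]']+$", low) && !(low %in% dict)) {
      low <- correct_spelling(low, dict)
    }
    expanded <- expand_abbreviations(low, abbreviations)
    surface <- c(surface, expanded)
    from_abbrev <- c(from_abbrev, rep(length(expanded) > 1, length(expanded)))
    emoji <- c(emoji, rep(FALSE, length(expanded)))
  }

  keep <- !emoji & !(surface %in% stopwords)
  surface <- surface[keep]
  from_abbrev <- from_abbrev[keep]
  lemma <- vapply(surface, lemmatize_token, character(1), USE.NAMES = FALSE)
  pos <- if (is.null(pos_tagger)) rep(NA_character_, length(surface)) else pos_tagger(surface)

  tokens <- tibble::tibble(
    surface = surface, lemma = lemma, pos = pos, from_abbrev = from_abbrev
  )
  ngrams <- build_ngrams(surface)
  list(
    clean_text = paste(surface, collapse = " "),
    tokens = tokens,
    ngrams = ngrams,
    hashtags = s$hashtags,
    mentions = s$mentions,
    urls = s$urls
  )
}

# Contiguous 1-, 2-, 3-grams over a token sequence; `start` is the 0-based
# index of the first token, spans are half-open [start, start + n).
build_ngrams <- function(tokens) {
  t_len <- length(tokens)
  if (t_len == 0) {
    return(tibble::tibble(ngram = character(), n = integer(), start = integer()))
  }
  rows <- list()
  for (n in 1:3) {
    if (t_len < n) break
    starts <- seq_len(t_len - n + 1) - 1L
    grams <- vapply(
      starts,
      function(s) paste(tokens[(s + 1):(s + n)], collapse = " "),
      character(1)
    )
    rows[[n]] <- tibble::tibble(ngram = grams, n = as.integer(n), start = starts)
  }
  dplyr::bind_rows(rows)
}

#' Normalize a tweet corpus
#'
#' Applies the full cleaning cascade (structural stripping, hashtag
#' splitting, repeat squeezing, spelling correction, abbreviation
#' expansion, tokenization with stop-word removal and lemmatization,
#' 1-3-gram construction) to every tweet.
#'
#' @param tweets tibble of tweets with at least `id` and `text` columns
#'   (as returned by [generate_corpus()] or [read_corpus_jsonl()]).
#' @param spelling character vector: the spelling dictionary.
#' @param abbreviations data frame with `abbreviation`, `expansion` columns.
#' @param stopwords character vector of stop words.
#' @param pos_tagger optional function `tokens -> tags` (pluggable;
#'   default assigns no tags).
#' @return tibble with one row per tweet: `id`, `clean_text`, list-columns
#'   `tokens` and `ngrams`, and extracted `hashtags`, `mentions`, `urls`.
#' @export
normalize_tweets <- function(tweets, spelling, abbreviations,
                             stopwords = default_stopwords(),
                             pos_tagger = NULL) {
  cleaned <- purrr::map(
    tweets$text,
    normalize_text,
    spelling = spelling,
    abbreviations = abbreviations,
    stopwords = stopwords,
    pos_tagger = pos_tagger
  )
  tibble::tibble(
    id = tweets$id,
    clean_text = purrr::map_chr(cleaned, "clean_text"),
    tokens = purrr::map(cleaned, "tokens"),
    ngrams = purrr::map(cleaned, "ngrams"),
    hashtags = purrr::map(cleaned, "hashtags"),
    mentions = purrr::map(cleaned, "mentions"),
    urls = purrr::map(cleaned, "urls")
  )
}
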