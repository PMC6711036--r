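# Valence-lexicon sentiment scoring. A lexicon- and rule-based scorer in
# the VADER family: token valences are summed after rule adjustments
# (negation, boosters, exclamation emphasis, all-caps emphasis) and the sum
# is normalized to [-1, +1] via x / sqrt(x^2 + alpha). Scoring operates on
# the raw tweet text by default, since cleaning destroys the emphasis cues.

SENTIMENT_ALPHA <- 15
NEGATION_FACTOR <- -0.74
BOOSTER_INCREMENT <- 0.293
EXCLAIM_FACTOR <- 1.292
CAPS_FACTOR <- 1.5
NEGATION_SCOPE <- 3

NEGATION_WORDS <- c(
  "not", "no", "never", "none", "cannot", "cant", "can't", "dont",
  "don't", "doesnt", "doesn't", "isnt", "isn't", "wasnt", "wasn't",
  "wont", "won't", "without", "neither", "nor"
)
BOOSTER_WORDS <- c(
  "very", "extremely", "really", "so", "totally", "absolutely",
  "incredibly", "utterly", "completely", "hugely"
)

#' Default rule configuration for the sentiment scorer
#'
#' @return named list of rule constants and word lists; pass
#'   `rules = NULL` to [sentiment_score()] for a rule-free (pure
#'   lexicon-sum) configuration.
#' @export
default_sentiment_rules <- function() {
  list(
    negation_words = NEGATION_WORDS,
    booster_words = BOOSTER_WORDS,
    negation_factor = NEGATION_FACTOR,
    booster_increment = BOOSTER_INCREMENT,
    exclaim_factor = EXCLAIM_FACTOR,
    caps_factor = CAPS_FACTOR,
    negation_scope = NEGATION_SCOPE
  )
}

#' Compound sentiment score of a text
#'
#' Sums the valence of every lexicon word, adjusted by rules: a negation
#' within the 3 preceding tokens flips the valence by a factor of -0.74; a
#' booster word in the same window adds 0.293 toward the word's sign; an
#' all-caps sentiment word is scaled by 1.5;
#' two or more trailing exclamation marks scale the final sum by 1.292.
#' The adjusted sum `s` is normalized to `s / sqrt(s^2 + 15)`, bounding the
#' compound score in `[-1, +1]`.
#'
#' @param text character vector of raw texts.
#' @param valence data frame with `term`, `score` columns (term valences).
#' @param rules rule configuration from [default_sentiment_rules()], or
#'   `NULL` to disable all rule adjustments.
#' @return numeric vector of compound scores in `[-1, 1]`.
#' @examples
#' vlx <- data.frame(term = "good", score = 1.9)
#' sentiment_score(c("good", "not good"), vlx)
#' @export
sentiment_score <- function(text, valence, rules = default_sentiment_rules()) {
  scores <- setNames(valence$score, tolower(valence$term))
  vapply(text, function(tx) {
    if (is.na(tx) || !nzchar(tx)) {
      return(0)
    }
    raw_tokens <- strsplit(stringr::str_squish(tx), " ", fixed = TRUE)[[1]]
    words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw_tokens)
    low <- tolower(words)
    s <- 0
    for (k in seq_along(low)) {
      v <- scores[low[k]]
      if (is.na(v)) next
      v <- unname(v)
      if (!is.null(rules)) {
        if (words[k] == toupper(words[k]) && grepl("[[:alpha:]]", words[k])) {
          v <- v * rules$caps_factor
        }
        window <- low[max(1, k - rules$negation_scope):max(1, k - 1)]
        if (k > 1) {
          n_boost <- sum(window %in% rules$booster_words)
          if (n_boost > 0) {
            v <- v + sign(v) * n_boost * rules$booster_increment
          }
          if (any(window %in% rules$negation_words)) {
            v <- v * rules$negation_factor
          }
        }
      }
      s <- s + v
    }
    if (!is.null(rules) && grepl("!{2,}$", tx)) {
      s <- s * rules$exclaim_factor
    }
    compound <- s / sqrt(s^2 + SENTIMENT_ALPHA)
    max(-1, min(1, compound))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Three-way polarity label for a compound score
#'
#' `compound >= 0.05` is positive, `<= -0.05` negative, otherwise neutral
#' (the conventional cut for compound-score classifiers).
#'
#' @param compound numeric vector of compound scores in `[-1, 1]`.
#' @return character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
sentiment_label <- function(compound) {
  stopifnot(all(compound >= -1 - 1e-12 & compound <= 1 + 1e-12))
  dplyr::case_when(
    compound >= 0.05 ~ "positive",
    compound <= -0.05 ~ "negative",
    TRUE ~ "neutral"
  )
}

#' Score the sentiment of every tweet in a corpus
#'
#' @param tweets tweet tibble (raw text is scored; set `use_clean_text`
#'   and pass a normalized corpus to score cleaned text instead, for
#'   auditing).
#' @param valence valence lexicon (`term`, `score`).
#' @param rules rule configuration (see [sentiment_score()]).
#' @param clean optional normalized corpus from [normalize_tweets()].
#' @param use_clean_text score `clean$clean_text` instead of raw text.
#' @return tibble: `tweet_id`, `compound`, `label`.
#' @export
score_corpus <- function(tweets, valence, rules = default_sentiment_rules(),
                         clean = NULL, use_clean_text = FALSE) {
  txt <- if (use_clean_text) {
    stopifnot(!is.null(clean))
    clean$clean_text[match(tweets$id, clean$id)]
  } else {
    tweets$text
  }
  compound <- sentiment_score(txt, valence, rules)
  tibble::tibble(
    tweet_id = tweets$id,
    compound = compound,
    label = sentiment_label(compound)
  )
}
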