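# User characterization: two-step gender inference (name dictionary, then a
# pluggable face classifier), the organization / patient / expert rule
# cascade, and gazetteer geolocation disambiguated by time zone and UTC
# offset. Age estimation is deliberately out of scope.

#' Default keyword configuration for the account cascade
#'
#' The cascade keyword lists are open-ended in practice ("eg" lists); they
#' ship here as an editable configuration seeded with the canonical
#' examples: non-personal organization cues, first-person pronouns and
#' their possessive/reflexive variants, person abbreviations, and
#' expert-related keywords.
#'
#' @return named list of character vectors: `nonpersonal`, `pronouns`,
#'   `person_abbrev`, `expert`.
#' @export
default_profile_keywords <- function() {
  list(
    nonpersonal = c("official", "news", "info", "pharma", "foundation",
                    "charity", "association", "society"),
    pronouns = c("i", "im", "i'm", "ive", "i've", "me", "my", "mine",
                 "myself", "we", "us", "our", "ours", "ourselves"),
    person_abbrev = c("mr", "mrs", "ms", "miss", "sir", "madam"),
    expert = c("dr", "prof", "professor", "md", "phd", "doctor")
  )
}

#' Organization cues found in display names
#'
#' Country names, country codes and continents used by the first
#' organization rule (a geographic token in the account name), plus URL
#' domain suffixes for the second rule.
#'
#' @param gazetteer optional gazetteer tibble; its countries/continents are
#'   added to the built-in code list.
#' @return list with `geo_terms` and `domain_pattern`.
#' @export
default_org_name_terms <- function(gazetteer = NULL) {
  geo <- c("uk", "usa", "us", "eu")
  if (!is.null(gazetteer)) {
    geo <- c(geo, tolower(unique(gazetteer$country)),
             tolower(unique(gazetteer$continent)))
  }
  list(
    geo_terms = unique(geo),
    domain_pattern = "\\.(org|com|net|gov|edu|io|co\\.uk)\\b"
  )
}

#' Deterministic stub image classifier
#'
#' Satisfies the pluggable face-classifier contract
#' (`image reference -> "female" | "male" | "no-face"`) by parsing
#' references of the form `"face:female"` / `"face:male"`; anything else
#' (including missing references) is `"no-face"`. A production deployment
#' would plug a trained face model in through the same contract.
#'
#' @param image_ref character image reference (or `NA`).
#' @return `"female"`, `"male"` or `"no-face"`.
#' @export
stub_image_classifier <- function(image_ref) {
  if (is.null(image_ref) || is.na(image_ref)) {
    return("no-face")
  }
  if (identical(image_ref, "face:female")) return("female")
  if (identical(image_ref, "face:male")) return("male")
  "no-face"
}

#' Infer a user's gender
#'
#' Two-step strategy: the first whitespace-delimited token of the display
#' name is checked against the gender-name table; a unique (non-ambiguous)
#' hit resolves the gender. Otherwise, if a profile image exists, the
#' pluggable image classifier is applied (`no-face` gives `unknown`).
#' Without an image the gender is `unknown`.
#'
#' @param display_name user display name.
#' @param has_profile_image logical.
#' @param name_table tibble with `name`, `gender`, `ambiguous` columns.
#' @param image_classifier function `image_ref -> {"female","male","no-face"}`.
#' @param image_ref image reference forwarded to the classifier.
#' @return `"female"`, `"male"` or `"unknown"`.
#' @export
infer_gender <- function(display_name, has_profile_image, name_table,
                         image_classifier = stub_image_classifier,
                         image_ref = NA_character_) {
  first <- tolower(strsplit(stringr::str_squish(display_name %||% ""), " ")[[1]][1])
  if (!is.na(first) && nzchar(first)) {
    hit <- name_table[name_table$name == first, ]
    if (nrow(hit) == 1 && !hit$ambiguous && hit$gender %in% c("female", "male")) {
      return(hit$gender)
    }
  }
  if (isTRUE(has_profile_image)) {
    res <- image_classifier(image_ref)
    if (res %in% c("female", "male")) {
      return(res)
    }
  }
  "unknown"
}

word_tokens <- function(x) {
  x <- tolower(x %||% "")
  toks <- strsplit(gsub("[^[:alnum:]']+", " ", x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

has_emoji_or_emoticon <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) {
    return(FALSE)
  }
  stringr::str_detect(x, stringr::regex(EMOJI_PATTERN)) ||
    any(vapply(ASCII_EMOTICONS, function(e) grepl(e, x, fixed = TRUE), logical(1)))
}

#' Classify an account as organization, patient, expert or unknown
#'
#' Organization checks fire first, in order: (1) a country, country code or
#' continent in the display name; (2) a URL domain in the name (e.g.
#' `.org`); (3) non-personal keywords in the description (official, news,
#' info, pharma, ...). If none fire, individual checks follow in order:
#' (1) resolved gender; (2) contributor/translator flag; (3) first-person
#' pronouns in the description; (4) emoji or emoticons in the description;
#' (5) person abbreviations (Mr, Ms, ...). An individual whose description
#' contains expert keywords (Dr, Prof, MD, PhD, ...) as whole tokens is an
#' `expert`, otherwise a `patient`. If nothing fires the type is
#' `unknown`. Exactly one matched rule is recorded for audit.
#'
#' @param user list or one-row data frame with `display_name`,
#'   `description`, `is_contributor`.
#' @param gender the user's inferred gender (from [infer_gender()]).
#' @param keywords keyword configuration, see [default_profile_keywords()].
#' @param org_terms organization name cues, see [default_org_name_terms()].
#' @return list with `account_type` and `matched_rule`.
#' @export
classify_account <- function(user, gender,
                             keywords = default_profile_keywords(),
                             org_terms = default_org_name_terms()) {
  name <- tolower(user$display_name %||% "")
  desc <- tolower(user$description %||% "")
  desc_tokens <- word_tokens(desc)

  # organization cascade
  geo_hit <- any(vapply(
    org_terms$geo_terms,
    function(g) grepl(paste0("\\b", g, "\\b"), name), logical(1)
  ))
  if (geo_hit) {
    return(list(account_type = "organization", matched_rule = "org:geo_in_name"))
  }
  if (grepl(org_terms$domain_pattern, name)) {
    return(list(account_type = "organization", matched_rule = "org:domain_in_name"))
  }
  if (any(desc_tokens %in% keywords$nonpersonal)) {
    return(list(account_type = "organization", matched_rule = "org:keyword"))
  }

  # individual cascade
  ind_rule <- NULL
  if (gender %in% c("female", "male")) {
    ind_rule <- "ind:gender"
  } else if (isTRUE(user$is_contributor)) {
    ind_rule <- "ind:contributor"
  } else if (any(desc_tokens %in% keywords$pronouns)) {
    ind_rule <- "ind:pronoun"
  } else if (has_emoji_or_emoticon(user$description %||% "")) {
    ind_rule <- "ind:emoji"
  } else if (any(desc_tokens %in% keywords$person_abbrev)) {
    ind_rule <- "ind:person_abbrev"
  }

  if (is.null(ind_rule)) {
    return(list(account_type = "unknown", matched_rule = "none"))
  }
  if (any(desc_tokens %in% keywords$expert)) {
    return(list(account_type = "expert",
                matched_rule = paste0(ind_rule, "+expert")))
  }
  list(account_type = "patient", matched_rule = ind_rule)
}

#' Resolve a free-text location against a gazetteer
#'
#' The location text is normalized (case, punctuation) and alias-expanded
#' (e.g. `NYC` -> `new york city`), then matched against gazetteer names.
#' A unique match resolves immediately; multiple matches are filtered by
#' time zone, then by UTC offset. If several candidates in different
#' countries remain, the location is unknown.
#'
#' @param location_text free-text location (may be `NA`).
#' @param time_zone user's time zone string (may be `NA`).
#' @param utc_offset user's UTC offset in seconds (may be `NA`).
#' @param gazetteer tibble with `name`, `country`, `continent`,
#'   `time_zone`, `utc_offset`.
#' @param aliases optional tibble with `alias`, `name` columns.
#' @return list with `city`, `country`, `continent` (all `NA` when
#'   unresolved).
#' @export
resolve_location <- function(location_text, time_zone, utc_offset, gazetteer,
                             aliases = NULL) {
  unresolved <- list(city = NA_character_, country = NA_character_,
                     continent = NA_character_)
  if (is.null(location_text) || is.na(location_text) || !nzchar(location_text)) {
    return(unresolved)
  }
  q <- stringr::str_squish(tolower(gsub("[^[:alnum:][:space:]]", " ", location_text)))
  if (!is.null(aliases)) {
    hit <- match(q, aliases$alias)
    if (!is.na(hit)) q <- aliases$name[hit]
  }
  cand <- gazetteer[gazetteer$name == q, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(unresolved)
  }
  if (nrow(cand) > 1 && !is.null(time_zone) && !is.na(time_zone)) {
    tz_cand <- cand[cand$time_zone == time_zone, , drop = FALSE]
    if (nrow(tz_cand) >= 1) cand <- tz_cand
  }
  if (nrow(cand) > 1 && !is.null(utc_offset) && !is.na(utc_offset)) {
    off_cand <- cand[cand$utc_offset == utc_offset, , drop = FALSE]
    if (nrow(off_cand) >= 1) cand <- off_cand
  }
  if (length(unique(cand$country)) > 1) {
    return(unresolved)
  }
  list(city = cand$name[1], country = cand$country[1],
       continent = cand$continent[1])
}

#' Profile every user in a corpus
#'
#' Runs gender inference, the account-type cascade and geolocation for each
#' user record.
#'
#' @param users tibble of user records (see [generate_corpus()]).
#' @param fixtures fixture list providing `name_gender`, `gazetteer` and
#'   optionally `aliases`.
#' @param image_classifier pluggable face classifier
#'   (default [stub_image_classifier()]).
#' @param keywords cascade keyword configuration.
#' @return tibble: `screen_name`, `gender`, `account_type`, `city`,
#'   `country`, `continent`, `matched_rule`.
#' @export
profile_users <- function(users, fixtures,
                          image_classifier = stub_image_classifier,
                          keywords = default_profile_keywords()) {
  org_terms <- default_org_name_terms(fixtures$gazetteer)
  aliases <- fixtures$aliases
  purrr::pmap_dfr(users, function(screen_name, display_name, description,
                                  location_text, time_zone, utc_offset,
                                  has_profile_image, image_ref,
                                  is_contributor, ...) {
    gender <- infer_gender(display_name, has_profile_image,
                           fixtures$name_gender, image_classifier, image_ref)
    cls <- classify_account(
      list(display_name = display_name, description = description,
           is_contributor = is_contributor),
      gender, keywords = keywords, org_terms = org_terms
    )
    loc <- resolve_location(location_text, time_zone, utc_offset,
                            fixtures$gazetteer, aliases)
    tibble::tibble(
      screen_name = screen_name,
      gender = gender,
      account_type = cls$account_type,
      city = loc$city,
      country = loc$country,
      continent = loc$continent,
      matched_rule = cls$matched_rule
    )
  })
}
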