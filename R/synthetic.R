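# Synthetic tweet corpus with planted ground truth. The generator emulates
# the study conditions of an archived bowel-disease tweet collection
# (Feb-Aug 2018): user-type and gender mixes, non-English fraction,
# per-category mention rates, planted misspellings, a May-June event window
# with inflated interaction counts, and auxiliary fixtures (gazetteer,
# gender-name table, abbreviation/spelling dictionaries, five-category term
# lexicon, valence lexicon). Everything downstream is measured against the
# planted truth.

#' Configuration for the synthetic corpus generator
#'
#' Defaults mirror the study conditions of the bowel-disease collection the
#' package is designed around: tweets from 2018-02-01 to 2018-08-31, ~4.1%
#' non-English, a user mix dominated by patients (58.6%), gender mix among
#' individuals of roughly 36% female / 50% male / 14% unresolvable,
#' per-category mention rates proportional to the observed category shares
#' (Disease 35.6%, Food and Diet 25.4%, Symptom 17.7%, Treatment 14.8%,
#' Drug 6.4%), a 52/14/34 negative/neutral/positive sentiment mix, and an
#' awareness-event window in May-June with inflated retweet/favorite
#' counts.
#'
#' @param n_tweets number of tweets to generate.
#' @param n_users number of distinct users.
#' @param date_range length-2 character/Date vector (start, end), UTC.
#' @param frac_non_english fraction of tweets tagged with a non-English
#'   language.
#' @param user_type_mix named proportions over
#'   `organization`, `patient`, `expert`, `unknown` (sums to 1).
#' @param gender_mix named proportions over `female`, `male`, `unknown`
#'   applied to individual (patient/expert) users.
#' @param mention_rate_per_category named numeric: mean planted lexicon
#'   mentions per tweet for each of the five meta-categories.
#' @param misspell_rate fraction of planted terms perturbed by a
#'   single-character corruption.
#' @param sentiment_mix named proportions over `negative`, `neutral`,
#'   `positive`.
#' @param event_window list with `start`, `end` (dates) and
#'   `interaction_multiplier >= 1` applied to interaction counts of tweets
#'   inside the window; `NULL` disables the event.
#' @param tweets_per_user_geom_prob success probability of the geometric
#'   distribution behind the long-tailed tweets-per-user profile.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   corpora.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_tweets = 2000,
                             n_users = 500,
                             date_range = c("2018-02-01", "2018-08-31"),
                             frac_non_english = 0.041,
                             user_type_mix = c(organization = 0.15, patient = 0.586,
                                               expert = 0.10, unknown = 0.164),
                             gender_mix = c(female = 0.36, male = 0.50, unknown = 0.14),
                             mention_rate_per_category = c(
                               "Disease" = 0.47, "Symptom" = 0.24,
                               "Food and Diet" = 0.34, "Treatment" = 0.20,
                               "Drug" = 0.09),
                             misspell_rate = 0.1,
                             sentiment_mix = c(negative = 0.52, neutral = 0.14,
                                               positive = 0.34),
                             event_window = list(start = "2018-05-01",
                                                 end = "2018-06-30",
                                                 interaction_multiplier = 3.5),
                             tweets_per_user_geom_prob = 0.35,
                             seed = 42) {
  cfg <- list(
    n_tweets = as.integer(n_tweets),
    n_users = as.integer(n_users),
    date_range = as.POSIXct(paste(date_range, c("00:00:00", "23:59:59")),
                            tz = "UTC"),
    frac_non_english = frac_non_english,
    user_type_mix = user_type_mix,
    gender_mix = gender_mix,
    mention_rate_per_category = mention_rate_per_category,
    misspell_rate = misspell_rate,
    sentiment_mix = sentiment_mix,
    event_window = event_window,
    tweets_per_user_geom_prob = tweets_per_user_geom_prob,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  check_props <- function(p, what, expected_names) {
    if (!setequal(names(p), expected_names)) {
      stop(what, " must be named over {", paste(expected_names, collapse = ", "),
           "}", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " proportions must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (cfg$n_tweets < 1 || cfg$n_users < 1) {
    stop("n_tweets and n_users must be positive", call. = FALSE)
  }
  if (cfg$date_range[1] >= cfg$date_range[2]) {
    stop("date_range start must precede end", call. = FALSE)
  }
  if (cfg$frac_non_english < 0 || cfg$frac_non_english > 1 ||
      cfg$misspell_rate < 0 || cfg$misspell_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  check_props(cfg$user_type_mix, "user_type_mix",
              c("organization", "patient", "expert", "unknown"))
  check_props(cfg$gender_mix, "gender_mix", c("female", "male", "unknown"))
  check_props(cfg$sentiment_mix, "sentiment_mix",
              c("negative", "neutral", "positive"))
  if (!setequal(names(cfg$mention_rate_per_category), META_CATEGORIES)) {
    stop("mention_rate_per_category must be named over the five meta-categories",
         call. = FALSE)
  }
  if (!is.null(cfg$event_window)) {
    if (cfg$event_window$interaction_multiplier < 1) {
      stop("event interaction_multiplier must be >= 1", call. = FALSE)
    }
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Fixtures

SYN_FEMALE_NAMES <- c("Mary", "Emma", "Sarah", "Lucy", "Sophia", "Olivia",
                      "Grace", "Hannah", "Chloe", "Laura")
SYN_MALE_NAMES <- c("John", "James", "David", "Michael", "Robert", "Thomas",
                    "Peter", "Daniel", "Mark", "Paul")
SYN_AMBIGUOUS_NAMES <- c("Alex", "Sam", "Taylor", "Jordan", "Casey", "Robin")

syn_gazetteer <- function() {
  tibble::tribble(
    ~name, ~country, ~continent, ~time_zone, ~utc_offset,
    "london", "United Kingdom", "Europe", "Europe/London", 0L,
    "manchester", "United Kingdom", "Europe", "Europe/London", 0L,
    "new york city", "United States", "America", "America/New_York", -18000L,
    "chicago", "United States", "America", "America/Chicago", -21600L,
    "toronto", "Canada", "America", "America/Toronto", -18000L,
    "sydney", "Australia", "Australia", "Australia/Sydney", 36000L,
    "melbourne", "Australia", "Australia", "Australia/Melbourne", 36000L,
    # same name, different time zones: resolvable by time zone
    "guadalajara", "Spain", "Europe", "Europe/Madrid", 3600L,
    "guadalajara", "Mexico", "America", "America/Mexico_City", -21600L,
    # same name, same time zone, different countries: must stay unknown
    "georgetown", "United States", "America", "America/New_York", -18000L,
    "georgetown", "Canada", "America", "America/New_York", -18000L,
    "mumbai", "India", "Asia", "Asia/Kolkata", 19800L,
    "dhaka", "Bangladesh", "Asia", "Asia/Dhaka", 21600L,
    "manila", "Philippines", "Asia", "Asia/Manila", 28800L,
    "cape town", "South Africa", "Africa", "Africa/Johannesburg", 7200L,
    "dublin", "Ireland", "Europe", "Europe/Dublin", 0L
  )
}

syn_location_aliases <- function() {
  tibble::tribble(
    ~alias, ~name,
    "nyc", "new york city",
    "new york", "new york city"
  )
}

syn_name_gender <- function() {
  dplyr::bind_rows(
    tibble::tibble(name = tolower(SYN_FEMALE_NAMES), gender = "female", ambiguous = FALSE),
    tibble::tibble(name = tolower(SYN_MALE_NAMES), gender = "male", ambiguous = FALSE),
    tibble::tibble(name = tolower(SYN_AMBIGUOUS_NAMES), gender = "unknown", ambiguous = TRUE)
  )
}

syn_abbreviations <- function() {
  tibble::tribble(
    ~abbreviation, ~expansion,
    "sbbos", "small bowel bacterial overgrowth syndrome",
    "ibs", "irritable bowel syndrome",
    "ibd", "inflammatory bowel disease",
    "uc", "ulcerative colitis",
    "gf", "gluten free"
  )
}

syn_lexicon_raw <- function() {
  tibble::tribble(
    ~term, ~source,
    # Disease (DOID); nested pair: "bowel disease" in "inflammatory bowel disease"
    "inflammatory bowel disease", "DOID",
    "bowel disease", "DOID",
    "irritable bowel syndrome", "DOID",
    "crohn disease", "DOID",
    "ulcerative colitis", "DOID",
    "celiac disease", "DOID",
    "anxiety disorder", "DOID",
    "depression", "DOID",
    "diarrhea", "DOID",
    "constipation", "DOID",
    "cancer", "DOID",
    "arthritis", "DOID",
    "asthma", "DOID",
    "fibromyalgia", "DOID",
    "obesity", "DOID",
    "heart disease", "DOID",
    "multiple sclerosis", "DOID",
    # Symptom (SYMP); nested pair: "abdominal pain" in "chronic abdominal pain"
    "chronic abdominal pain", "SYMP",
    "abdominal pain", "SYMP",
    "pain", "SYMP",
    "bloating", "SYMP",
    "flatulence", "SYMP",
    "nausea", "SYMP",
    "fatigue", "SYMP",
    "cramping", "SYMP",
    # Food and Diet (FoodOn); nested pair: "gluten free" in "gluten free diet"
    "gluten free diet", "FoodOn",
    "gluten free", "FoodOn",
    "gluten", "FoodOn",
    "probiotic", "FoodOn",
    "dietary supplement", "FoodOn",
    "vitamin d", "FoodOn",
    "fiber", "FoodOn",
    "magnesium", "FoodOn",
    "iron", "FoodOn",
    "barley", "FoodOn",
    "psyllium", "FoodOn",
    "ginger", "FoodOn",
    # Treatment (NCIT interventions); nested: "bowel resection" in "partial ..."
    "partial bowel resection", "NCIT-Intervention",
    "bowel resection", "NCIT-Intervention",
    "hypnotherapy", "NCIT-Intervention",
    "surgery", "NCIT-Intervention",
    "dietary intervention", "NCIT-Intervention",
    "colonoscopy", "NCIT-Intervention",
    "stress management", "NCIT-Intervention",
    # Drug (DrugBank); nested pair: "medical cannabis" in "medical cannabis oil"
    "medical cannabis oil", "DrugBank",
    "medical cannabis", "DrugBank",
    "cannabidiol", "DrugBank",
    "loperamide", "DrugBank",
    "lactulose", "DrugBank",
    "glutamine", "DrugBank",
    "plantago seed", "DrugBank",
    "ginger", "DrugBank" # deliberate cross-category duplicate; purged on build
  ) |>
    dplyr::mutate(category = map_meta_category(.data$source))
}

syn_valence <- function() {
  tibble::tribble(
    ~term, ~score,
    "great", 3.1, "hopeful", 1.9, "wonderful", 2.7, "relief", 1.5,
    "love", 3.2, "amazing", 2.8, "good", 1.9, "happy", 2.7,
    "awful", -3.4, "horrible", -2.9, "hate", -2.7, "terrible", -3.0,
    "miserable", -2.6, "bad", -2.5, "sad", -2.1, "worse", -2.1
  )
}

SYN_CLAUSES <- list(
  positive = c("feeling great and hopeful today",
               "such wonderful progress and relief",
               "i love the amazing support here"),
  negative = c("an awful and horrible week so far",
               "i hate this terrible flare",
               "feeling miserable and bad today"),
  neutral = c("sharing a routine update",
              "weekly journal entry for the record",
              "another diary note from the logbook")
)

SYN_CONNECTORS <- c("and", "with", "plus", "alongside")

SYN_URLS <- c(
  "https://guts4life.example.org/ibd",
  "https://ibdnews.example.com/article1",
  "https://gutscience.example.org/paper2",
  "https://boweltrust.example.org/campaign",
  "https://glutenfreelife.example.com/post7",
  "https://cannabiscare.example.com/shop",
  "https://nutritionlab.example.org/study3",
  "https://healthline.example.com/symptoms",
  "https://crohnshelp.example.org/guide",
  "https://probioticshub.example.com/review",
  "https://stomalife.example.org/stories",
  "https://journalclub.example.org/gi"
)

syn_spelling <- function() {
  lex_tokens <- unlist(strsplit(syn_lexicon_raw()$term, " ", fixed = TRUE))
  abb <- syn_abbreviations()
  clause_tokens <- unlist(strsplit(unlist(SYN_CLAUSES), " ", fixed = TRUE))
  extra <- c(
    "probiotics", "supplements", "symptoms", "diets", "laxatives",
    "gut", "health", "journey", "living", "daily", "updates", "research",
    "community", "awareness", "story", "stories", "tips", "questions",
    "doctor", "hospital", "treatment", "disease", "diet", "flare", "today"
  )
  sort(unique(c(
    lex_tokens, abb$abbreviation, unlist(strsplit(abb$expansion, " ", fixed = TRUE)),
    clause_tokens, SYN_CONNECTORS, default_stopwords(), extra
  )))
}

#' Generate the auxiliary fixtures for a synthetic run
#'
#' Produces the lookup tables every pipeline stage needs: a gazetteer
#' (including one city name resolvable only by time zone and one that must
#' stay unknown), a gender-name table with ambiguous entries, abbreviation
#' and spelling dictionaries, the five-category term lexicon (with nested
#' bigram/trigram pairs per category and one deliberate cross-category
#' duplicate), a valence lexicon, stop words, and location aliases.
#'
#' @param config a [synthetic_config()] (fixtures are deterministic and do
#'   not consume randomness; the config is accepted for interface symmetry).
#' @return named list of tibbles/vectors: `gazetteer`, `name_gender`,
#'   `abbreviations`, `spelling`, `lexicon`, `valence`, `stopwords`,
#'   `aliases`.
#' @export
generate_fixtures <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  list(
    gazetteer = syn_gazetteer(),
    name_gender = syn_name_gender(),
    abbreviations = syn_abbreviations(),
    spelling = syn_spelling(),
    lexicon = syn_lexicon_raw(),
    valence = syn_valence(),
    stopwords = default_stopwords(),
    aliases = syn_location_aliases()
  )
}

# ---------------------------------------------------------------------------
# Users

# Inverse abbreviation map (expansion -> abbreviation) for hashtag variants.
syn_abbrev_inverse <- function(abbreviations) {
  setNames(toupper(abbreviations$abbreviation), abbreviations$expansion)
}

ORG_NAME_STEMS <- c("Gut Health", "Bowel Trust", "IBD Support", "Colitis Care",
                    "Digestive Wellness", "Crohns Alliance")
ORG_KEYWORD_DESCS <- c(
  "official news and info on bowel disease research",
  "news and awareness campaigns, official account",
  "pharma updates and official research info"
)
UNKNOWN_DESCS <- c("", "daily posts", "random thoughts", "")

syn_build_users <- function(cfg, fixtures) {
  n <- cfg$n_users
  types <- sample(names(cfg$user_type_mix), n, replace = TRUE,
                  prob = cfg$user_type_mix)
  is_individual <- types %in% c("patient", "expert")
  genders <- rep("unknown", n)
  genders[is_individual] <- sample(names(cfg$gender_mix), sum(is_individual),
                                   replace = TRUE, prob = cfg$gender_mix)

  gaz <- fixtures$gazetteer
  resolvable <- gaz |>
    dplyr::add_count(.data$name, .data$time_zone) |>
    dplyr::filter(.data$n == 1) |>
    dplyr::select(-"n")
  unresolvable_name <- "georgetown"

  screen_name <- sprintf("u%04d", seq_len(n))
  display_name <- character(n)
  description <- character(n)
  location_text <- rep(NA_character_, n)
  time_zone <- rep(NA_character_, n)
  utc_offset <- rep(NA_integer_, n)
  has_image <- rep(FALSE, n)
  image_ref <- rep(NA_character_, n)
  contributor <- rep(FALSE, n)
  true_country <- rep(NA_character_, n)
  planted_rule <- character(n)

  female_pool <- SYN_FEMALE_NAMES
  male_pool <- SYN_MALE_NAMES

  for (i in seq_len(n)) {
    type <- types[i]
    if (type == "organization") {
      cue <- sample(c("name_country", "name_domain", "keyword"), 1)
      stem <- sample(ORG_NAME_STEMS, 1)
      if (cue == "name_country") {
        display_name[i] <- paste(stem, sample(unique(gaz$country), 1))
        description[i] <- "supporting the community since 2010"
      } else if (cue == "name_domain") {
        display_name[i] <- paste0(tolower(gsub(" ", "", stem)), ".org")
        description[i] <- "resources for the bowel disease community"
      } else {
        display_name[i] <- paste(stem, "Network")
        description[i] <- sample(ORG_KEYWORD_DESCS, 1)
      }
      planted_rule[i] <- paste0("org:", cue)
    } else if (type %in% c("patient", "expert")) {
      g <- genders[i]
      if (g %in% c("female", "male")) {
        via_image <- runif(1) < 0.25
        if (via_image) {
          display_name[i] <- paste(sample(SYN_AMBIGUOUS_NAMES, 1), "Walker")
          has_image[i] <- TRUE
          image_ref[i] <- paste0("face:", g)
          planted_rule[i] <- "gender:image"
        } else {
          first <- if (g == "female") sample(female_pool, 1) else sample(male_pool, 1)
          display_name[i] <- paste(first, "Walker")
          planted_rule[i] <- "gender:name"
        }
      } else {
        # unknown gender: individual status must come from another cue
        display_name[i] <- paste(sample(SYN_AMBIGUOUS_NAMES, 1), "Walker")
        planted_rule[i] <- "gender:none"
      }
      if (type == "patient") {
        if (g == "unknown") {
          cue <- sample(c("pronoun", "emoji", "contributor"), 1)
          if (cue == "pronoun") {
            description[i] <- "i share my daily life since the diagnosis"
          } else if (cue == "emoji") {
            description[i] <- "fighting the flare every day \U0001F4AA"
          } else {
            description[i] <- "gut stories, one day at a time"
            contributor[i] <- TRUE
          }
          planted_rule[i] <- paste(planted_rule[i], paste0("ind:", cue), sep = ";")
        } else {
          description[i] <- sample(c(
            "i am living with crohn and sharing my journey",
            "my gut, my story, one day at a time",
            "living with colitis, sharing what helps me"
          ), 1)
          planted_rule[i] <- paste(planted_rule[i], "ind:gender", sep = ";")
        }
      } else { # expert
        base <- if (g == "unknown") {
          "md and researcher, i study gut disorders"
        } else {
          sample(c(
            "dr in gastroenterology, i help my patients",
            "md and phd, i study the microbiome",
            "prof of nutrition, i write about the gut"
          ), 1)
        }
        description[i] <- base
        planted_rule[i] <- paste(planted_rule[i], "ind:expert", sep = ";")
      }
    } else { # unknown type
      display_name[i] <- paste0("Cloud", sample(100:999, 1))
      description[i] <- sample(UNKNOWN_DESCS, 1)
      planted_rule[i] <- "none"
    }

    # location: ~60% resolvable, ~8% ambiguous-unresolvable, rest absent
    u <- runif(1)
    if (u < 0.60) {
      row <- resolvable[sample(nrow(resolvable), 1), ]
      location_text[i] <- if (row$name == "new york city" && runif(1) < 0.5) "NYC" else row$name
      time_zone[i] <- row$time_zone
      utc_offset[i] <- row$utc_offset
      true_country[i] <- row$country
    } else if (u < 0.68) {
      location_text[i] <- unresolvable_name
      time_zone[i] <- "America/New_York"
      utc_offset[i] <- -18000L
    }
  }

  users <- tibble::tibble(
    screen_name = screen_name,
    display_name = display_name,
    description = description,
    location_text = location_text,
    time_zone = time_zone,
    utc_offset = utc_offset,
    has_profile_image = has_image,
    image_ref = image_ref,
    is_contributor = contributor
  )
  truth <- tibble::tibble(
    screen_name = screen_name,
    type = types,
    gender = genders,
    country = true_country,
    planted_rule = planted_rule
  )
  list(users = users, truth = truth)
}

# ---------------------------------------------------------------------------
# Tweets

# Corrupt one token of a planted term by a single-character substitution;
# the result is guaranteed to differ from the original and to be absent
# from the spelling dictionary.
syn_perturb_term <- function(term, spelling) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  wi <- which.max(nchar(words))
  w <- words[wi]
  pos <- max(2, ceiling(nchar(w) / 2))
  for (repl in c("x", "q", "z")) {
    cand <- paste0(substr(w, 1, pos - 1), repl, substr(w, pos + 1, nchar(w)))
    if (cand != w && !(cand %in% spelling)) {
      words[wi] <- cand
      return(list(text = paste(words, collapse = " "), original = w, perturbed = cand))
    }
  }
  words[wi] <- paste0(w, "x")
  list(text = paste(words, collapse = " "), original = w,
       perturbed = words[wi])
}

# CamelCase hashtag form of a term ("anxiety disorder" -> "AnxietyDisorder").
syn_camel <- function(term) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  paste(paste0(toupper(substr(words, 1, 1)), substr(words, 2, nchar(words))),
        collapse = "")
}

#' Generate a synthetic tweet corpus with planted ground truth
#'
#' Draws users (types, genders, locations, rule-conforming descriptions),
#' then tweets with planted lexicon mentions, misspellings, hashtags,
#' user mentions/replies/retweets, URLs, and polarity-bearing clauses.
#' Identical configs (including seed) give identical output.
#'
#' @param config a [synthetic_config()].
#' @param fixtures fixtures from [generate_fixtures()]; regenerated when
#'   omitted.
#' @return list with `tweets` (tibble), `users` (tibble), `truth` (list
#'   with `users` and `tweets` tibbles), and the `fixtures` used.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            fixtures = generate_fixtures(config)) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  cfg <- config

  ub <- syn_build_users(cfg, fixtures)
  users <- ub$users
  truth_users <- ub$truth

  lex <- build_lexicon(fixtures$lexicon)
  plantable <- lex$entries
  abbrev_inv <- syn_abbrev_inverse(fixtures$abbreviations)

  # long-tailed author profile: geometric weights over a shuffled user order
  w <- stats::dgeom(seq_len(cfg$n_users) - 1, cfg$tweets_per_user_geom_prob) + 1e-9
  w <- sample(w)
  authors <- sample(users$screen_name, cfg$n_tweets, replace = TRUE, prob = w)

  org_users <- truth_users$screen_name[truth_users$type == "organization"]
  target_pool <- users$screen_name
  target_w <- ifelse(target_pool %in% org_users, 6, 1)

  n <- cfg$n_tweets
  t0 <- as.numeric(cfg$date_range[1])
  t1 <- as.numeric(cfg$date_range[2])
  created <- sort(as.POSIXct(runif(n, t0, t1), origin = "1970-01-01", tz = "UTC"))

  non_english <- runif(n) < cfg$frac_non_english
  polarity <- sample(names(cfg$sentiment_mix), n, replace = TRUE,
                     prob = cfg$sentiment_mix)

  in_window <- rep(FALSE, n)
  if (!is.null(cfg$event_window)) {
    ws <- as.POSIXct(paste(cfg$event_window$start, "00:00:00"), tz = "UTC")
    we <- as.POSIXct(paste(cfg$event_window$end, "23:59:59"), tz = "UTC")
    in_window <- created >= ws & created <= we
  }

  texts <- character(n)
  langs <- ifelse(non_english, sample(c("fr", "es", "de"), n, replace = TRUE), "en")
  hashtags <- vector("list", n)
  urls <- vector("list", n)
  mentions <- vector("list", n)
  reply_to <- rep(NA_character_, n)
  retweet_of <- rep(NA_character_, n)
  truth_mentions <- vector("list", n)
  truth_misspellings <- vector("list", n)

  for (i in seq_len(n)) {
    if (non_english[i]) {
      texts[i] <- "ceci est un message sans rapport avec le sujet"
      hashtags[[i]] <- character()
      urls[[i]] <- character()
      mentions[[i]] <- character()
      truth_mentions[[i]] <- tibble::tibble(term = character(),
                                            category = character(),
                                            perturbed = logical())
      truth_misspellings[[i]] <- tibble::tibble(original = character(),
                                                perturbed = character())
      next
    }

    planted <- list()
    for (cat in META_CATEGORIES) {
      k <- min(stats::rpois(1, cfg$mention_rate_per_category[[cat]]), 2L)
      if (k > 0) {
        pool <- plantable$term[plantable$category == cat]
        planted[[cat]] <- sample(pool, min(k, length(pool)))
      }
    }
    planted_terms <- as.character(unlist(planted, use.names = FALSE))
    planted_cats <- as.character(rep(names(planted), lengths(planted)))

    phrases <- character(length(planted_terms))
    pert_flag <- logical(length(planted_terms))
    miss <- list()
    for (j in seq_along(planted_terms)) {
      if (length(planted_terms) > 0 && runif(1) < cfg$misspell_rate) {
        p <- syn_perturb_term(planted_terms[j], fixtures$spelling)
        phrases[j] <- p$text
        pert_flag[j] <- TRUE
        miss[[length(miss) + 1]] <- tibble::tibble(original = p$original,
                                                   perturbed = p$perturbed)
      } else {
        phrases[j] <- planted_terms[j]
      }
    }

    clause <- sample(SYN_CLAUSES[[polarity[i]]], 1)
    body <- clause
    if (length(phrases) > 0) {
      conn <- sample(SYN_CONNECTORS, length(phrases), replace = TRUE)
      body <- paste(body, paste(paste(conn, phrases), collapse = " "))
    }

    tags <- character()
    if (length(planted_terms) > 0 && runif(1) < 0.35) {
      t_pick <- sample(planted_terms, 1)
      form <- sample(c("camel", "first", "abbrev"), 1)
      tag <- if (form == "abbrev" && t_pick %in% names(abbrev_inv)) {
        abbrev_inv[[t_pick]]
      } else if (form == "first") {
        strsplit(t_pick, " ", fixed = TRUE)[[1]][1]
      } else {
        syn_camel(t_pick)
      }
      tags <- tag
      body <- paste(body, paste0("#", tag))
    }

    ment <- character()
    r <- runif(1)
    target <- sample(target_pool, 1, prob = target_w)
    if (r < 0.25 && target != authors[i]) {
      ment <- target
      body <- paste(body, paste0("@", target))
    } else if (r < 0.33 && target != authors[i]) {
      reply_to[i] <- target
    } else if (r < 0.45 && target != authors[i]) {
      retweet_of[i] <- target
    }

    u <- character()
    if (runif(1) < 0.2) {
      u <- sample(SYN_URLS, 1)
      body <- paste(body, u)
    }

    texts[i] <- body
    hashtags[[i]] <- tags
    urls[[i]] <- u
    mentions[[i]] <- ment
    tm <- tibble::tibble(term = planted_terms, category = planted_cats,
                         perturbed = pert_flag)
    truth_mentions[[i]] <- dplyr::distinct(tm, .data$term, .keep_all = TRUE)
    truth_misspellings[[i]] <- if (length(miss)) dplyr::bind_rows(miss) else
      tibble::tibble(original = character(), perturbed = character())
  }

  base_rt <- rnbinom(n, size = 0.6, mu = 2)
  base_fav <- rnbinom(n, size = 0.6, mu = 3)
  mult <- ifelse(in_window, cfg$event_window$interaction_multiplier %||% 1, 1)
  retweet_count <- as.integer(round(base_rt * mult))
  favorite_count <- as.integer(round(base_fav * mult))

  tweets <- tibble::tibble(
    id = sprintf("t%06d", seq_len(n)),
    screen_name = authors,
    text = texts,
    lang = langs,
    created_at = created,
    retweet_count = retweet_count,
    favorite_count = favorite_count,
    reply_to = reply_to,
    retweet_of = retweet_of,
    hashtags = hashtags,
    mentions = mentions,
    urls = urls
  )

  truth_tweets <- tibble::tibble(
    id = tweets$id,
    lang = langs,
    polarity = polarity,
    in_event_window = in_window,
    mentions = truth_mentions,
    misspellings = truth_misspellings
  )

  list(
    tweets = tweets,
    users = users,
    truth = list(users = truth_users, tweets = truth_tweets),
    fixtures = fixtures
  )
}

# ---------------------------------------------------------------------------
# Serialization

#' Write a corpus as JSON lines
#'
#' One compact JSON object per tweet using a minimal subset of the
#' historical Twitter API v1.1 field names (`id_str`, `text`, `lang`,
#' `created_at`, counts, `entities`, embedded `user` record), so archived
#' real data can flow through the same reader.
#'
#' @param corpus list with `tweets` and `users` tibbles (see
#'   [generate_corpus()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  users <- corpus$users
  user_recs <- setNames(
    purrr::pmap(users, function(screen_name, display_name, description,
                                location_text, time_zone, utc_offset,
                                has_profile_image, image_ref, is_contributor) {
      list(
        screen_name = screen_name,
        name = display_name,
        description = description,
        location = if (is.na(location_text)) NULL else location_text,
        time_zone = if (is.na(time_zone)) NULL else time_zone,
        utc_offset = if (is.na(utc_offset)) NULL else utc_offset,
        has_profile_image = has_profile_image,
        image_ref = if (is.na(image_ref)) NULL else image_ref,
        contributor_enabled = is_contributor
      )
    }),
    users$screen_name
  )
  recs <- purrr::pmap(corpus$tweets, function(id, screen_name, text, lang,
                                              created_at, retweet_count,
                                              favorite_count, reply_to,
                                              retweet_of, hashtags, mentions,
                                              urls) {
    list(
      id_str = id,
      text = text,
      lang = lang,
      created_at = format(created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      retweet_count = retweet_count,
      favorite_count = favorite_count,
      in_reply_to_screen_name = if (is.na(reply_to)) NULL else reply_to,
      retweeted_status_screen_name = if (is.na(retweet_of)) NULL else retweet_of,
      entities = list(
        hashtags = as.list(hashtags),
        urls = as.list(urls),
        user_mentions = as.list(mentions)
      ),
      user = user_recs[[screen_name]]
    )
  })
  write_jsonl(recs, path)
}

#' Read a JSON-lines corpus
#'
#' Inverse of [write_corpus_jsonl()]: reconstructs the `tweets` and `users`
#' tibbles from a JSONL archive.
#'
#' @param path JSONL file path.
#' @return list with `tweets` and `users` tibbles.
#' @export
read_corpus_jsonl <- function(path) {
  recs <- read_jsonl(path)
  tweets <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      id = r$id_str,
      screen_name = r$user$screen_name,
      text = r$text,
      lang = r$lang,
      created_at = as.POSIXct(r$created_at, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"),
      retweet_count = as.integer(r$retweet_count),
      favorite_count = as.integer(r$favorite_count),
      reply_to = r$in_reply_to_screen_name %||% NA_character_,
      retweet_of = r$retweeted_status_screen_name %||% NA_character_,
      hashtags = list(as.character(unlist(r$entities$hashtags))),
      mentions = list(as.character(unlist(r$entities$user_mentions))),
      urls = list(as.character(unlist(r$entities$urls)))
    )
  })
  users <- purrr::map_dfr(recs, function(r) {
    u <- r$user
    tibble::tibble(
      screen_name = u$screen_name,
      display_name = u$name,
      description = u$description %||% "",
      location_text = u$location %||% NA_character_,
      time_zone = u$time_zone %||% NA_character_,
      utc_offset = as.integer(u$utc_offset %||% NA_integer_),
      has_profile_image = isTRUE(u$has_profile_image),
      image_ref = u$image_ref %||% NA_character_,
      is_contributor = isTRUE(u$contributor_enabled)
    )
  }) |>
    dplyr::distinct(.data$screen_name, .keep_all = TRUE)
  list(tweets = tweets, users = users)
}

#' Write fixtures as TSV files
#'
#' @param fixtures list from [generate_fixtures()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  tsv(fixtures$gazetteer, "gazetteer")
  tsv(fixtures$name_gender, "name_gender")
  tsv(fixtures$abbreviations, "abbreviations")
  tsv(tibble::tibble(word = fixtures$spelling), "spelling")
  tsv(fixtures$lexicon, "lexicon")
  tsv(fixtures$valence, "valence")
  tsv(tibble::tibble(word = fixtures$stopwords), "stopwords")
  tsv(fixtures$aliases, "aliases")
  invisible(dir)
}

#' Read fixtures from a directory of TSV files
#'
#' @param dir directory written by [write_fixtures()].
#' @return named fixture list (see [generate_fixtures()]).
#' @export
read_fixtures <- function(dir) {
  tsv <- function(name, col_types) {
    readr::read_tsv(file.path(dir, paste0(name, ".tsv")),
                    col_types = col_types, progress = FALSE)
  }
  list(
    gazetteer = tsv("gazetteer", "cccci"),
    name_gender = tsv("name_gender", "ccl"),
    abbreviations = tsv("abbreviations", "cc"),
    spelling = tsv("spelling", "c")$word,
    lexicon = tsv("lexicon", "ccc"),
    valence = tsv("valence", "cd"),
    stopwords = tsv("stopwords", "c")$word,
    aliases = tsv("aliases", "cc")
  )
}
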