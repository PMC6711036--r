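# Lexicon construction for entity recognition. Terms come from five source
# vocabularies (DOID, SYMP, FoodOn, the NCIT intervention branch, DrugBank)
# rolled up into five meta-categories.

#' Map a source vocabulary to its meta-category
#'
#' @param source_vocabulary one of `"DOID"`, `"SYMP"`, `"FoodOn"`,
#'   `"NCIT-Intervention"`, `"DrugBank"` (vectorized).
#' @return character vector of meta-categories (`"Disease"`, `"Symptom"`,
#'   `"Food and Diet"`, `"Treatment"`, `"Drug"`).
#' @examples
#' map_meta_category("DOID")
#' @export
map_meta_category <- function(source_vocabulary) {
  out <- SOURCE_TO_CATEGORY[source_vocabulary]
  if (anyNA(out)) {
    bad <- unique(source_vocabulary[is.na(out)])
    stop("unknown source vocabulary: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# Term normalization shared by lexicon construction and hashtag matching:
# lowercase, special characters (incl. hyphens) to spaces, single-spaced.
normalize_term <- function(term) {
  term <- tolower(term)
  term <- gsub("[^[:alnum:][:space:]]", " ", term)
  stringr::str_squish(term)
}

#' Build a recognition lexicon from raw term entries
#'
#' Applies the preprocessing rules in order: lowercase all terms, collapse
#' extra whitespace, drop terms shorter than 2 or longer than 280
#' characters, replace special characters (including hyphens) by a space,
#' and remove any term associated with more than one meta-category (both
#' entries are purged). A lemma variant index is built so that lemmatized
#' tweet n-grams can still hit canonical terms.
#'
#' @param raw_entries data frame with columns `term`, `source`, `category`
#'   (category may be omitted; it is then derived from `source` via
#'   [map_meta_category()]).
#' @return an object of class `bd_lexicon`: a list with `entries` (tibble
#'   `term`, `source`, `category`) and `lemma_index` (tibble `lemma_term`,
#'   `term`).
#' @export
build_lexicon <- function(raw_entries) {
  if (is.null(raw_entries) || nrow(raw_entries) == 0) {
    warning("empty lexicon input", call. = FALSE)
    entries <- tibble::tibble(term = character(), source = character(), category = character())
    return(structure(
      list(entries = entries,
           lemma_index = tibble::tibble(lemma_term = character(), term = character())),
      class = "bd_lexicon"
    ))
  }
  raw_entries <- tibble::as_tibble(raw_entries)
  if (!"category" %in% names(raw_entries)) {
    raw_entries$category <- map_meta_category(raw_entries$source)
  }

  entries <- raw_entries |>
    dplyr::mutate(
      term = stringr::str_squish(tolower(.data$term)),
      term = normalize_term(.data$term)
    ) |>
    dplyr::filter(nchar(.data$term) >= 2, nchar(.data$term) <= 280) |>
    dplyr::distinct(.data$term, .data$category, .keep_all = TRUE)

  # cross-category duplicates are ambiguous: purge every entry of the term
  multi <- entries |>
    dplyr::count(.data$term) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$term)
  entries <- dplyr::filter(entries, !(.data$term %in% multi)) |>
    dplyr::select("term", "source", "category")

  lemma_index <- entries |>
    dplyr::mutate(
      lemma_term = vapply(
        strsplit(.data$term, " ", fixed = TRUE),
        function(ws) paste(vapply(ws, lemmatize_token, character(1)), collapse = " "),
        character(1)
      )
    ) |>
    dplyr::filter(.data$lemma_term != .data$term) |>
    dplyr::distinct(.data$lemma_term, .keep_all = TRUE) |>
    dplyr::select("lemma_term", "term")

  structure(list(entries = entries, lemma_index = lemma_index), class = "bd_lexicon")
}

#' @export
print.bd_lexicon <- function(x, ...) {
  cat("<bd_lexicon> ", nrow(x$entries), " terms in ",
      length(unique(x$entries$category)), " categories\n", sep = "")
  print(dplyr::count(x$entries, .data$category))
  invisible(x)
}
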