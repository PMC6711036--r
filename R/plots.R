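# ggplot2 views of the summary tables.

#' Plot monthly posting and interaction activity
#'
#' Bars for tweet counts with a line for interaction volume (retweets +
#' favorites), the usual way monthly activity with an event spike is shown.
#'
#' @param rows tibble from [monthly_activity()].
#' @return a ggplot object.
#' @export
plot_monthly_activity <- function(rows) {
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_tweets), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_interactions, group = 1),
                       color = "firebrick", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_interactions),
                        color = "firebrick") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Monthly tweets (bars) and interactions (line)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the sentiment distribution by semantic category
#'
#' Stacked proportional bars of negative / neutral / positive tweet counts
#' per meta-category.
#'
#' @param rows tibble from [sentiment_by_category()].
#' @return a ggplot object.
#' @export
plot_sentiment_by_category <- function(rows) {
  long <- rows |>
    dplyr::select("meta_category", "n_negative", "n_neutral", "n_positive") |>
    tidyr::pivot_longer(-"meta_category", names_to = "label",
                        values_to = "n") |>
    dplyr::mutate(label = sub("^n_", "", .data$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$meta_category, y = .data$n,
                                     fill = .data$label)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(negative = "#c0392b",
                                          neutral = "#7f8c8d",
                                          positive = "#27ae60")) +
    ggplot2::labs(x = NULL, y = "share of tweets", fill = NULL,
                  title = "Tweet sentiment by semantic category") +
    ggplot2::theme_minimal()
}

#' Plot the top terms of the term-frequency table
#'
#' @param rows tibble from [term_frequency_table()].
#' @param top_n how many terms to show (default 15).
#' @return a ggplot object.
#' @export
plot_term_frequency <- function(rows, top_n = 15) {
  top <- utils::head(rows, top_n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$term, .data$n_tweets),
    y = .data$n_tweets, fill = .data$meta_category
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "tweets mentioning the term", fill = "category",
                  title = "Most mentioned terms") +
    ggplot2::theme_minimal()
}
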