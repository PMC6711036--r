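# Network representation and analysis: a directed user-interaction graph
# (mentions + retweets, optionally replies-as-mentions) and an undirected
# term co-occurrence graph with majority-sentiment edges. Metrics follow
# the standard normalized definitions; igraph does the heavy lifting.

#' Build the user interaction graph
#'
#' Directed edges run from the tweeting user to each mentioned user and to
#' the author of a retweeted status (information flows toward the target's
#' in-degree); replies count as mentions by default since a reply embeds
#' one. Edge weight is the number of such interactions over the corpus.
#'
#' @param tweets tweet tibble (list-column `mentions`, columns `reply_to`,
#'   `retweet_of`).
#' @param profiles optional profile tibble; attaches `account_type` as a
#'   node attribute.
#' @param include_replies count replies as mentions (default `TRUE`).
#' @return an `igraph` (classes `bd_interaction_graph`, `igraph`) with
#'   edge attribute `weight`.
#' @export
build_interaction_graph <- function(tweets, profiles = NULL,
                                    include_replies = TRUE) {
  edges <- purrr::pmap_dfr(
    list(tweets$screen_name, tweets$mentions, tweets$reply_to, tweets$retweet_of),
    function(src, ment, rep, rt) {
      targets <- as.character(ment)
      if (include_replies && !is.na(rep)) targets <- c(targets, rep)
      if (!is.na(rt)) targets <- c(targets, rt)
      if (length(targets) == 0) {
        return(NULL)
      }
      tibble::tibble(from = src, to = targets)
    }
  )
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    agg <- dplyr::count(edges, .data$from, .data$to, name = "weight")
    g <- igraph::graph_from_data_frame(agg, directed = TRUE)
  }
  if (!is.null(profiles) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, profiles$screen_name)
    igraph::V(g)$account_type <- ifelse(is.na(idx), "unknown",
                                        profiles$account_type[idx])
  }
  class(g) <- c("bd_interaction_graph", class(g))
  g
}

#' Build the term co-occurrence graph
#'
#' Two terms share an undirected edge whenever they are mentioned in the
#' same tweet; the weight counts co-occurring tweets. Each edge carries the
#' modal sentiment label of its contributing tweets (`sentiment_majority`;
#' ties give `neutral`). Node attribute `n_tweets` counts the tweets
#' mentioning the term.
#'
#' @param mentions mention tibble from [recognize_corpus()] (deduplicated
#'   per tweet/term).
#' @param sentiments sentiment tibble from [score_corpus()] (optional; no
#'   majority labels without it).
#' @return an `igraph` (classes `bd_cooccurrence_graph`, `igraph`).
#' @export
build_cooccurrence_graph <- function(mentions, sentiments = NULL) {
  mentions <- dplyr::distinct(mentions, .data$tweet_id, .data$term)
  pairs <- mentions |>
    dplyr::group_by(.data$tweet_id) |>
    dplyr::reframe({
      terms <- sort(unique(.data$term))
      if (length(terms) < 2) {
        tibble::tibble(a = character(), b = character())
      } else {
        cmb <- utils::combn(terms, 2)
        tibble::tibble(a = cmb[1, ], b = cmb[2, ])
      }
    })
  if (nrow(pairs) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    class(g) <- c("bd_cooccurrence_graph", class(g))
    return(g)
  }
  if (!is.null(sentiments)) {
    pairs <- dplyr::left_join(
      pairs, sentiments[, c("tweet_id", "label")], by = "tweet_id"
    )
  } else {
    pairs$label <- NA_character_
  }
  agg <- pairs |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      weight = dplyr::n(),
      sentiment_majority = modal_label(.data$label),
      .groups = "drop"
    )
  g <- igraph::graph_from_data_frame(agg, directed = FALSE)
  counts <- dplyr::count(mentions, .data$term)
  idx <- match(igraph::V(g)$name, counts$term)
  igraph::V(g)$n_tweets <- counts$n[idx]
  class(g) <- c("bd_cooccurrence_graph", class(g))
  g
}

# Modal sentiment label; any tie (including none recorded) -> neutral.
modal_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) {
    return("neutral")
  }
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1) "neutral" else winners
}

#' Per-node topology metrics
#'
#' Standard normalized definitions: degree centrality `deg / (n - 1)`;
#' betweenness normalized by the number of ordered (directed graphs) or
#' unordered (undirected) node pairs excluding the node; closeness as the
#' component-wise `(reachable - 1) / sum(distances)`; local clustering
#' coefficient `2 * triangles / (deg * (deg - 1))` on the undirected
#' projection. Isolated or single nodes score 0.
#'
#' @param graph an igraph (interaction or co-occurrence graph).
#' @return tibble with one row per node: `name`, `in_degree`,
#'   `out_degree`, `degree_centrality`, `betweenness`, `closeness`,
#'   `clustering`.
#' @export
graph_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(tibble::tibble(
      name = character(), in_degree = numeric(), out_degree = numeric(),
      degree_centrality = numeric(), betweenness = numeric(),
      closeness = numeric(), clustering = numeric()
    ))
  }
  directed <- igraph::is_directed(graph)
  deg_in <- igraph::degree(graph, mode = "in")
  deg_out <- igraph::degree(graph, mode = "out")
  deg_all <- igraph::degree(graph, mode = "all")
  und <- if (directed) igraph::as_undirected(graph, mode = "collapse") else graph

  if (n == 1) {
    betw <- 0
    clos <- 0
    dc <- 0
  } else {
    dc <- deg_all / (n - 1)
    betw <- igraph::betweenness(graph, directed = directed, normalized = TRUE,
                                weights = NA)
    d <- igraph::distances(graph, mode = if (directed) "out" else "all",
                           weights = NA)
    clos <- apply(d, 1, function(row) {
      finite <- row[is.finite(row)]
      r <- length(finite) # includes self (distance 0)
      if (r <= 1) 0 else (r - 1) / sum(finite)
    })
  }
  clust <- igraph::transitivity(und, type = "local", isolates = "zero")

  tibble::tibble(
    name = igraph::V(graph)$name %||% as.character(seq_len(n)),
    in_degree = as.numeric(deg_in),
    out_degree = as.numeric(deg_out),
    degree_centrality = as.numeric(dc),
    betweenness = as.numeric(betw),
    closeness = as.numeric(clos),
    clustering = as.numeric(clust)
  )
}

#' Graph-level summary metrics
#'
#' @param graph an igraph.
#' @return one-row tibble: `n_nodes`, `n_edges`,
#'   `characteristic_path_length` (mean shortest path over connected
#'   pairs), `average_neighbors` (mean degree).
#' @export
graph_summary <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L,
                          characteristic_path_length = NA_real_,
                          average_neighbors = NA_real_))
  }
  directed <- igraph::is_directed(graph)
  d <- igraph::distances(graph, mode = if (directed) "out" else "all",
                         weights = NA)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  cpl <- if (length(finite) == 0) NA_real_ else mean(finite)
  tibble::tibble(
    n_nodes = n,
    n_edges = igraph::ecount(graph),
    characteristic_path_length = cpl,
    average_neighbors = mean(igraph::degree(graph, mode = "all"))
  )
}

#' Extract communities as large connected components
#'
#' Communities are operationalized as weakly-connected components with
#' more than `min_size` members, sorted by size (descending). An optional
#' modularity-based detection (Louvain on the undirected projection) is
#' available behind a flag.
#'
#' @param graph an igraph.
#' @param min_size components must have strictly more than this many
#'   nodes (default 5).
#' @param method `"components"` (default) or `"louvain"`.
#' @return tibble: `community` (id), `size`, `members` (list-column of
#'   node names).
#' @export
extract_communities <- function(graph, min_size = 5, method = c("components", "louvain")) {
  method <- match.arg(method)
  empty <- tibble::tibble(community = integer(), size = integer(),
                          members = list())
  if (igraph::vcount(graph) == 0) {
    return(empty)
  }
  membership <- if (method == "components") {
    igraph::components(graph, mode = "weak")$membership
  } else {
    und <- if (igraph::is_directed(graph)) {
      igraph::as_undirected(graph, mode = "collapse")
    } else {
      graph
    }
    igraph::cluster_louvain(und)$membership
  }
  names_v <- igraph::V(graph)$name %||% as.character(seq_along(membership))
  comm <- tibble::tibble(name = names_v, community = as.integer(membership)) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(size = dplyr::n(), members = list(.data$name),
                     .groups = "drop") |>
    dplyr::filter(.data$size > min_size) |>
    dplyr::arrange(dplyr::desc(.data$size)) |>
    dplyr::mutate(community = dplyr::row_number())
  if (nrow(comm) == 0) empty else comm
}

#' @rdname bd-graph-tidiers
#' @param x a `bd_interaction_graph` or `bd_cooccurrence_graph`.
#' @param ... unused.
#' @return for `tidy()`, the edge list as a tibble; for `glance()`, the
#'   one-row graph summary of [graph_summary()].
#' @exportS3Method generics::tidy
tidy.bd_interaction_graph <- function(x, ...) {
  df <- igraph::as_data_frame(x, what = "edges")
  tibble::as_tibble(df)
}

#' @rdname bd-graph-tidiers
#' @exportS3Method generics::tidy
tidy.bd_cooccurrence_graph <- function(x, ...) {
  df <- igraph::as_data_frame(x, what = "edges")
  tibble::as_tibble(df)
}

#' @rdname bd-graph-tidiers
#' @exportS3Method generics::glance
glance.bd_interaction_graph <- function(x, ...) {
  graph_summary(x)
}

#' @rdname bd-graph-tidiers
#' @exportS3Method generics::glance
glance.bd_cooccurrence_graph <- function(x, ...) {
  graph_summary(x)
}

#' Export a graph as edge-list TSV and GraphML
#'
#' @param graph an igraph.
#' @param path_prefix file path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.graphml`.
#' @return the prefix, invisibly.
#' @export
export_graph <- function(graph, path_prefix) {
  edges <- tibble::as_tibble(igraph::as_data_frame(graph, what = "edges"))
  readr::write_tsv(edges, paste0(path_prefix, ".tsv"), progress = FALSE)
  igraph::write_graph(graph, paste0(path_prefix, ".graphml"), format = "graphml")
  invisible(path_prefix)
}
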