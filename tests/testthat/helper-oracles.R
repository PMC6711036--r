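# Independent brute-force oracles used to cross-check the implementation.

# Levenshtein distance by the full dynamic-programming matrix.
oracle_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m
  D[1, ] <- 0:n
  if (m > 0 && n > 0) {
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        D[i + 1, j + 1] <- min(
          D[i, j + 1] + 1L,
          D[i + 1, j] + 1L,
          D[i, j] + as.integer(A[i] != B[j])
        )
      }
    }
  }
  D[m + 1, n + 1]
}

# Brute-force entity matcher: enumerate every contiguous 1-3-token window,
# look it up (surface, then lemma, then lemma variant index), then resolve
# overlaps by sorting all candidates longest-first / leftmost-first and
# greedily accepting those whose tokens are still free.
oracle_recognize <- function(tokens, lexicon) {
  t_len <- nrow(tokens)
  empty <- data.frame(term = character(), start = integer(), n = integer())
  if (t_len == 0) {
    return(empty)
  }
  cands <- list()
  for (s in seq_len(t_len)) {
    for (n in 1:3) {
      e <- s + n - 1
      if (e > t_len) next
      key_s <- paste(tokens$surface[s:e], collapse = " ")
      key_l <- paste(tokens$lemma[s:e], collapse = " ")
      canon <- NULL
      if (key_s %in% lexicon$entries$term) {
        canon <- key_s
      } else if (key_l %in% lexicon$entries$term) {
        canon <- key_l
      } else if (key_l %in% lexicon$lemma_index$lemma_term) {
        canon <- lexicon$lemma_index$term[
          match(key_l, lexicon$lemma_index$lemma_term)
        ]
      }
      if (!is.null(canon)) {
        cands[[length(cands) + 1]] <- data.frame(
          term = canon, start = s - 1L, n = as.integer(n)
        )
      }
    }
  }
  if (length(cands) == 0) {
    return(empty)
  }
  df <- do.call(rbind, cands)
  df <- df[order(-df$n, df$start), , drop = FALSE]
  used <- rep(FALSE, t_len)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    span <- (df$start[i] + 1):(df$start[i] + df$n[i])
    if (!any(used[span])) {
      keep[i] <- TRUE
      used[span] <- TRUE
    }
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Brute-force graph metrics from an adjacency matrix (no igraph).
# Floyd-Warshall distances, shortest-path counts by DP over distance,
# betweenness by the sigma(s,v)*sigma(v,t) decomposition, clustering by
# direct triangle counting on the undirected projection.
oracle_graph_metrics <- function(adj, directed) {
  n <- nrow(adj)
  A <- (adj > 0) * 1
  if (!directed) A <- pmax(A, t(A))
  und <- pmax(A, t(A))

  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }

  # sigma[s, t]: number of shortest s->t paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    finite_d <- d[s, ]
    for (dist in sort(unique(finite_d[is.finite(finite_d) & finite_d > 0]))) {
      for (v in which(finite_d == dist)) {
        preds <- which(A[, v] == 1 & finite_d == dist - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }

  betw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == v || t == v || s == t) next
        if (!directed && s > t) next
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    betw[v] <- tot
  }
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  betw_norm <- if (denom > 0) betw / denom else rep(0, n)

  deg_in <- colSums(A)
  deg_out <- rowSums(A)
  deg_all <- if (directed) deg_in + deg_out else rowSums(und)

  clos <- vapply(seq_len(n), function(v) {
    row <- d[v, ]
    finite <- row[is.finite(row)]
    r <- length(finite)
    if (r <= 1) 0 else (r - 1) / sum(finite)
  }, numeric(1))

  clust <- vapply(seq_len(n), function(v) {
    nb <- which(und[v, ] == 1 & seq_len(n) != v)
    k <- length(nb)
    if (k < 2) {
      return(0)
    }
    links <- sum(und[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))

  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  cpl <- if (length(finite) == 0) NA_real_ else mean(finite)

  list(
    in_degree = as.numeric(deg_in),
    out_degree = as.numeric(deg_out),
    degree_centrality = if (n > 1) deg_all / (n - 1) else 0,
    betweenness = betw_norm,
    closeness = clos,
    clustering = clust,
    characteristic_path_length = cpl,
    average_neighbors = mean(deg_all)
  )
}

# igraph object from an adjacency matrix, named a1..an.
graph_from_adj <- function(adj, directed) {
  g <- igraph::graph_from_adjacency_matrix(
    adj, mode = if (directed) "directed" else "max"
  )
  igraph::V(g)$name <- paste0("a", seq_len(nrow(adj)))
  g
}

# Small normalized corpus + matching lexicon shared across NER tests.
tiny_lexicon <- function() {
  build_lexicon(data.frame(
    term = c("inflammatory bowel disease", "bowel disease", "diarrhea",
             "gluten free diet", "gluten free", "gluten", "probiotic",
             "abdominal pain", "pain"),
    source = c("DOID", "DOID", "DOID", "FoodOn", "FoodOn", "FoodOn",
               "FoodOn", "SYMP", "SYMP")
  ))
}

tokens_of <- function(...) {
  surface <- c(...)
  tibble::tibble(
    surface = surface,
    lemma = vapply(surface, bowelwatch:::lemmatize_token, character(1),
                   USE.NAMES = FALSE),
    pos = NA_character_,
    from_abbrev = FALSE
  )
}
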