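# bowelwatch

Infodemiology tooling for characterizing the bowel-disease (BD) community —
inflammatory bowel disease (IBD) and irritable bowel syndrome (IBS) — in
archived tweet collections. The package is aimed at health-communication
researchers and biomedical text-mining practitioners who want a tested,
reproducible version of the classic lexicon-based tweet-mining workflow:
who is talking (patients, experts, organizations; where they are), what
they talk about (five semantic categories of biomedical terms), how they
feel about it (valence-based sentiment), and how users and topics connect
(interaction and co-occurrence networks).

## What it computes

The pipeline chains seven stages, each exposed as tidyverse-style
functions (tibbles in, tibbles out):

1. **Synthetic corpus generation** — a seeded generator emits a JSONL tweet
   archive (minimal Twitter API v1.1 field subset) with planted ground
   truth: user types, genders, locations, lexicon mentions, misspellings,
   sentiment polarity, and an awareness-event window with inflated
   interaction counts. Every downstream stage is measurable against the
   planted truth without any data collection.
2. **Normalization** — structural stripping (mentions, URLs, `#` markers,
   special characters), hashtag splitting at case/digit boundaries
   (`InflammatoryBowelDisease` → *Inflammatory Bowel Disease*), squeezing
   of character runs ≥ 3 (`haaaapppyy` → `haappyy`), spelling correction by
   maximal normalized Levenshtein similarity
   `sim(a,b) = 1 − d(a,b) / max(|a|,|b|)`, abbreviation expansion
   (`SBBOS` → *small bowel bacterial overgrowth syndrome*), tokenization
   with stop-word removal and plural lemmatization, and contiguous
   1–3-gram construction.
3. **User profiling** — two-step gender inference (gender-name dictionary,
   then a pluggable face-classifier contract with a deterministic stub), a
   rule cascade for organization / patient / expert / unknown, and
   gazetteer geolocation disambiguated by time zone and UTC offset
   (*Guadalajara* resolves to Spain or Mexico by zone; same-name,
   same-zone cities in different countries stay unknown).
4. **Entity recognition** — inverted longest-match lookup: the tweet's own
   n-grams are keys into a lexicon of five source vocabularies rolled into
   meta-categories (DOID → Disease, SYMP → Symptom, FoodOn → Food and
   Diet, NCIT interventions → Treatment, DrugBank → Drug). Longest n-gram
   wins; leftmost wins among equals; matched tokens are consumed. Lemma
   and abbreviation variants are matched and flagged.
5. **Sentiment** — a lexicon-and-rule scorer in the VADER family: token
   valences, adjusted for negation (×−0.74 within 3 tokens), boosters
   (±0.293), all-caps emphasis (×1.5) and trailing `!!` (×1.292), summed
   and normalized to a compound score `s/√(s² + 15)` in [−1, +1];
   labels are positive (≥ +0.05), negative (≤ −0.05), else neutral.
6. **Networks** — a directed user-interaction graph (mentions + retweets,
   replies-as-mentions) and an undirected term co-occurrence graph with
   majority-sentiment edges; normalized degree / betweenness / closeness
   centralities, clustering coefficients, characteristic path length, and
   communities as connected components with > 5 members.
7. **Summary tables** — term frequency with hashtag-variant counting,
   sentiment by category (patient tweets), monthly activity with
   event-window uplift (`100 · mean(window) / mean(rest)`), URL tables by
   poster type, and geographic distributions. All percentages are
   `100·count/total` rounded half-up to two decimals.

## Worked example

```r
library(bowelwatch)

cfg <- synthetic_config(n_tweets = 500, n_users = 200, seed = 2018)
res <- run_pipeline(cfg)

head(res$tables$term_frequency, 5)
#>   term     meta_category n_tweets n_favorites n_retweets n_hashtags
#> 1 gluten   Food and Diet       24          97         63         11
#> 2 asthma   Disease             21          51         59          3
#> 3 psyllium Food and Diet       19          43         20          2
#> 4 diarrhea Disease             17          74         39          1
#> 5 fiber    Food and Diet       17          70         49          3

res$tables$monthly_activity
#>   month   n_tweets n_interactions
#> 1 2018-02       73            452
#> 2 2018-03       63            274
#> 3 2018-04       67            371
#> 4 2018-05       73           1196
#> 5 2018-06       66            949
#> 6 2018-07       73            332
#> 7 2018-08       68            350

event_uplift(res$tables$monthly_activity, c("2018-05", "2018-06"))
#> [1] 301
```

The term table counts, for each recognized term, the tweets mentioning it
and the engagement (favorites, retweets, hashtag uses) those tweets drew.
The monthly table shows the May–June event window: mean interactions in
the window are 301% of the mean over the other five months, the planted
awareness-event effect. Graph objects work with broom-style verbs:

```r
glance(res$interaction_graph)
#>   n_nodes n_edges characteristic_path_length average_neighbors
#> 1     113     179                       1.08              3.17

head(dplyr::arrange(graph_metrics(res$interaction_graph),
                    dplyr::desc(in_degree)), 1)
#>   name  in_degree out_degree degree_centrality betweenness closeness clustering
#> 1 u0087         6          0            0.0536           0         0      0.2
```

The highest in-degree node (`u0087`) is an organization account — the
structural signature of communities that direct questions at trusted
institutional accounts. `plot_monthly_activity()`,
`plot_sentiment_by_category()` and `plot_term_frequency()` give ggplot2
views of the tables.

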