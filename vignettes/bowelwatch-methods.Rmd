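---
title: "Methods: mining bowel-disease conversations from tweet archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining bowel-disease conversations from tweet archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowelwatch)
```

bowelwatch implements a lexicon-based infodemiology workflow for
bowel-disease (IBD/IBS) conversations on Twitter-like platforms. This
vignette documents the procedure, the parameters that matter, the design
choices made where the method is genuinely underdetermined, and what the
synthetic test bed does and does not demonstrate.

## The processing model

The pipeline treats a tweet archive as a fixed corpus (no live
collection) and runs seven stages in order. Each stage's output is a
tibble, so intermediate results can be inspected, filtered, or replaced.

**Ingest.** Records are deduplicated by id and filtered to `lang == "en"`.
The language tag is trusted; no language identification is attempted.

**Normalization cascade.** Cleaning operations run in a fixed order:
structural stripping → hashtag splitting → repeat squeezing → spelling
correction → abbreviation expansion → tokenization. The order matters in
two places. First, spelling correction runs *before* abbreviation
expansion so that a token the dictionary cannot explain still gets a
chance to expand; to keep the corrector from mangling known shorthand,
abbreviation keys are included in the spelling dictionary and therefore
pass through untouched. Second, hashtag bodies remain in the text when
the `#` marker is stripped, and the splitting stage then *replaces* the
in-place body with its split words — appending them instead would
double-count the tag's tokens in the n-gram stream.

Hashtag splitting is conservative: boundaries are inserted at
lower→upper case transitions, acronym boundaries, and letter↔digit
transitions, so `gutHealth2018` → `gut / Health / 2018`, while an
all-lowercase multiword tag stays unsplit (no dictionary segmentation).
Concatenating the pieces always reproduces the tag.

Spelling correction accepts the suggestion with the highest normalized
Levenshtein similarity, `1 − d(a,b)/max(|a|,|b|)`; the default suggester
proposes dictionary words within edit distance 2. Ties break to the
lexicographically smallest suggestion for reproducibility. Two empty
strings are defined to have similarity 1.

The tokenizer is deliberately simple: whitespace/punctuation splitting,
hyphen-to-space normalization (so `gluten-free` aligns with the lexicon's
`gluten free`), lowercase, a plural-stripping lemmatizer stub, stop-word
removal, and contiguous 1–3-grams. Part-of-speech tagging is a pluggable
interface with a no-op default, since nothing downstream requires tags.
Emoji survive cleaning as tokens (the profiler needs them in
descriptions) but are dropped before n-grams.

**User profiling.** Gender inference is two-step: the first
whitespace-delimited token of the display name is looked up in a
gender-name table (only unambiguous entries resolve), then a pluggable
image classifier is consulted if a profile image exists. The classifier
contract is `image ref → {female, male, no-face}`; the shipped
implementation is a deterministic stub that parses synthetic references,
standing in for a trained face model that is an external dependency by
design.

Account typing is a strict cascade. Organization rules fire first (a
geographic token in the name; a URL domain in the name; non-personal
keywords in the description), then individual rules (resolved gender;
contributor/translator flag; first-person pronouns; emoji or emoticons;
person abbreviations), and the expert check (`dr`, `prof`, `md`,
`phd`, ...) runs *only* for users that already passed an individual rule.
A user matching both organization and individual cues is therefore an
organization — cascade order resolves the ambiguity. Keyword lists are
open-ended in the field; they ship as editable configuration seeded with
the canonical examples. Exactly one matched rule is recorded per user for
audit. Age estimation is deliberately out of scope.

Geolocation normalizes the free-text location, expands aliases
(`NYC` → `new york city`), and matches gazetteer names. Multiple matches
are filtered by time zone, then UTC offset; if candidates in more than
one country survive, the location is unknown — never guessed.

**Entity recognition.** The lexicon is preprocessed by lowercasing,
whitespace collapsing, dropping terms shorter than 2 or longer than 280
characters, replacing special characters (including hyphens) with
spaces, and purging any term attached to more than one meta-category
(both entries go — a term that is simultaneously a food and a drug is
ambiguous at this granularity). Recognition is *inverted*: the tweet's
n-grams are lookup keys. Candidates are tested longest-first (3, 2, 1)
and leftmost-first within a length; accepted spans consume their tokens.
Beyond the longest-first preference, the leftmost tie-break and the
no-token-reuse rule are this package's choices; both are needed for a
deterministic matcher. Overlapping mentions are forbidden by default,
with a flag to allow cross-category overlaps. Mentions are counted once
per (tweet, term), the convention required for interpretable table
totals.

**Sentiment.** The scorer follows the standard compound-score contract
of lexicon-and-rule sentiment tools for social media: sum of token
valences with rule adjustments — negation within the 3 preceding tokens
multiplies by −0.74; boosters add 0.293 toward the word's sign; an
all-caps sentiment word scales by 1.5; two or more trailing exclamation
marks scale the final sum by 1.292 — normalized by `s/√(s² + α)` with
α = 15. The three-way cut at ±0.05 (inclusive) is the community-standard
convention. Scoring uses the *raw* text by default because cleaning
destroys the emphasis cues (caps, punctuation); a flag allows scoring
cleaned text for audits. A pluggable external scorer can be swapped in
for parity runs.

**Networks.** Interaction edges run tweeter → target for each mention
and retweet; replies count as mentions by default (a reply embeds one),
with a flag to exclude them. Retweet edges point at the original author,
so information sinks accumulate in-degree. Co-occurrence edges connect
every unordered pair of distinct terms in a tweet; each edge carries the
modal sentiment of its contributing tweets, with ties mapped to neutral.
Metrics use the standard normalized forms: degree centrality
`deg/(n−1)`; betweenness normalized over ordered (directed) or unordered
(undirected) pairs; closeness as the component-wise
`(reachable − 1)/Σ distances`, which is also what igraph computes for
disconnected graphs (isolates score 0); clustering on the undirected
projection; characteristic path length as the mean over connected pairs.
Communities are weakly-connected components with strictly more than 5
members (modularity-based detection is available behind a flag but not
the default, since component membership is what the downstream tables
need).

**Tables.** Every percentage is `100·count/total` rounded **half-up** to
two decimals, and uplifts round half-up to integers; this is the
convention that makes the canonical worked examples come out exactly
(54.00/16.00/30.00 for a 5691/1686/3161 row; 174 for means 3314 vs
1902). Reports in this genre occasionally truncate instead of rounding
in running text; such values differ in the last digit and are documented
rather than reproduced. Half-up rounding is implemented with a relative
1e-12 guard so that decimal counts like 1005/100000 (binary 100.4999…)
round as their exact decimal value would. Month bucketing is UTC. The
event uplift is `100 · mean(window)/mean(remaining months)` and requires
a non-empty complement. Hashtag-variant counting matches a split,
normalized, lemmatized hashtag to a term when either word sequence is a
prefix of the other (`#anxiety` counts toward *anxiety disorder*) or
when a single-token hashtag expands to the term via the abbreviation
dictionary (`#IBD`).

## The synthetic test bed

The generator's defaults encode the study conditions the package is
designed around: tweets from 2018-02-01 to 2018-08-31; ~4.1% non-English;
a user mix of 58.6% patients, 15% organizations, 10% experts, 16.4%
unknown; a gender mix among individuals of 36% female / 50% male / 14%
unresolvable; per-category mention rates proportional to category shares
of roughly 36/25/18/15/6 percent (Disease, Food and Diet, Symptom,
Treatment, Drug); a 52/14/34 negative/neutral/positive polarity mix; and
a May–June event window. Values the conditions do not pin down were
chosen once as field-plausible: a default scale of 2,000 tweets over 500
users, a geometric (long-tailed) tweets-per-user profile, a 0.1 misspell
rate, negative-binomial interaction counts with means 2 (retweets) and 3
(favorites), and an event multiplier of 3.5.

Texts are assembled from templates — a polarity-bearing clause, planted
lexicon terms joined by connectors, optional hashtags, user mentions,
replies, retweets and URLs — so ground-truth alignment is exact. User
descriptions are constructed to satisfy exactly the cascade rules of
their true type; a quarter of gendered individuals resolve via the image
stub rather than the name table; unknown-gender patients are split
across the pronoun, emoji and contributor cues so every individual rule
is exercised. The fixtures deliberately plant the hard cases: a
time-zone-resolvable duplicated city name and an unresolvable one, a
nested bigram/trigram lexicon pair in every category, a cross-category
duplicate term that must be purged, and the canonical abbreviation.

What passing tests show: the implementation recovers *constructed*
signals perfectly — rule-conforming profiles classify at 100%, planted
unperturbed mentions are all found, planted polarity is recovered, and
the matcher is exactly equivalent to a brute-force window oracle. What
they do not show: performance on real tweets, whose descriptions violate
cascade rules, whose misspellings are not single-character corruptions,
whose sentiment is not template-borne, and whose language tags lie. The
synthetic corpus validates the machinery, not the field accuracy of the
rules.

## Numerical choices and degenerate inputs

* Empty text yields empty structures everywhere; an all-stop-word tweet
  has zero tokens and zero n-grams.
* `normalized_levenshtein("", "")` is 1 by definition.
* Single-node and empty graphs: centralities are defined as 0;
  characteristic path length of an edgeless graph is `NA`.
* Sentiment of a text with no lexicon words is exactly 0 (neutral).
* Spell-correction ties break lexicographically; co-occurrence sentiment
  ties break to neutral; equal-length match candidates break leftmost.
* `share_percentage` refuses `total <= 0`; `event_uplift` refuses an
  empty baseline.

## Problem sizes used by the test suite

The suite exercises the properties at sizes chosen to make the checks
sharp but quick: oracle equivalence of the matcher on ~1,100 synthetic
tweets; profile recovery on 2,000 users; 100 random graphs of up to 12
nodes against the brute-force metrics oracle; 10,000 random texts for
the sentiment bound; 1,000 random string pairs for the edit-distance
oracle. The acceptance script measures recovery on a fresh corpus of
1,200 tweets and 2,000 users.

## Known limitations

* The face classifier and part-of-speech tagger are contracts with
  stubs; plugging real models in is the user's responsibility.
* The lemmatizer is a plural-stripping stub, not a morphological
  analyzer; lemma-variant matching is correspondingly shallow.
* Hashtag segmentation cannot split all-lowercase multiword tags.
* URL categorization (informative/scientific/health/commercial) was a
  manual judgment in the original workflow; the table carries a
  free-text category column fed by an optional domain mapping, defaulting
  to "uncategorized".
* Sentiment is three-way polarity only — no emotion taxonomy, no
  sarcasm handling.
* Geolocation resolves city names against a gazetteer; it does not
  geocode arbitrary strings, and it never returns a country absent from
  the gazetteer.
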