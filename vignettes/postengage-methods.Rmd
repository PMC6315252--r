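---
title: "Methods: dictionary classification and engagement analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary classification and engagement analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postengage)
```

## The problem

Administrators of health-communication pages — the motivating case is
Brazilian Facebook pages about cancer — publish a mix of content:
testimonies, donation appeals, commemorative dates, research news, event
announcements, institutional notes, risk-factor advice, beauty tips. The
recurring empirical finding is that the categories posted most are often
not the categories that engage the audience most. Seeing that requires two
ingredients: a way to put every post into a content category, and a way to
score audience engagement that is comparable across posts. `postengage`
implements both, plus the reporting, prediction and evaluation machinery
around them.

## The engagement model

Each post carries interaction counts. The engagement score is the linear
combination

$$E = \text{clicks} + 0.05\,\text{reactions} + 0.2\,\text{shares} + 0.75\,\text{comments},$$

and the engagement rate is $E/\text{reach}$ when reach (unique viewers, an
administrator-only metric) is known. The weights encode an effort
hierarchy: a reaction is one tap; a share means the user adopts the content
on their own timeline; a comment requires drafting text and taking a public
position, so it is weighted fifteen times a reaction. The weights are a
modelling choice, not an estimate; `engagement_weights()` makes them
explicit and overridable.

Two consequences of linearity are load-bearing and tested:

* **mean-of-scores = score-of-means.** A category's *weighted average
  engagement* can be computed from the category's mean reactions, shares
  and comments; `summarize_engagement()` does exactly that, so its output
  is directly comparable to published per-category summary tables.
* **public-data mode.** When clicks are unavailable (crawled public data),
  the clicks term is simply absent — not imputed as zero clicks being a
  claim about the world. Likewise `engagement_rate` is `NA`, never 0 or
  `Inf`, when reach is absent or zero.

Display rounding is half-up to one decimal (`round_half_up()`), with
computation at full precision. Reference tables in this field appear to
truncate in a few cells (e.g. an error rate of 20.858% printed as 20.8%);
we document one consistent convention rather than mimic truncation
artifacts.

## The classifier

The dictionary maps category names to sets of **complete word forms**, and
these sets must be pairwise disjoint — a word can belong to one category
only. Classification is occurrence counting: tokenize the post text,
count, for each category, how many token occurrences fall in its keyword
set, and assign the argmax. A keyword appearing twice counts twice; this
matters in practice because a short post repeating one commemorative word
can outvote a single keyword of its true topic, and that failure mode is
exactly what per-category error breakdowns surface.

Deliberate design choices, each of which was genuinely open:

* **Normalization** (`normalize_word()`): Unicode NFC plus lowercase
  folding, **diacritics preserved**. Stripping accents could merge distinct
  Portuguese words ("câncer" vs a hypothetical "cancer" loanword), so the
  minimal transformation wins. Dictionary words and text tokens go through
  the identical function.
* **Tokenization** (`tokenize()`): maximal runs of Unicode letters after
  URL removal; digits and punctuation never enter tokens; internal hyphens
  split ("pré-natal" → "pré", "natal"). This is the simplest defensible
  reading of complete-word matching and is documented so users can
  re-tokenize upstream if they disagree.
* **No morphology.** Singular/plural and gender variants must be
  enumerated in the dictionary (`expand_inflections()` helps normalize a
  hand-written list). There is deliberately no stemming: the matcher does
  not consider compound or root words.
* **Ties**: resolved deterministically (alphabetical by default, or a
  user-supplied priority list) and *flagged* (`tie = TRUE`), so ambiguity
  is visible in reports instead of silently absorbed.
* **All-zero posts** get `UNCATEGORIZED` rather than a forced label;
  forcing one would contaminate per-category summaries.
* **Occurrences vs distinct keywords**: whether the matcher should count
  repeated occurrences or distinct matched types is a real fork; we count
  occurrences (the error analyses this design comes from imply repeated
  words drive the decision) and expose the counts so either view can be
  recomputed.

The classifier has no notion of context, negation, irony or typos. A post
*about* quitting smoking and a post joking about cigarettes look identical
to it. These are intrinsic limits of dictionary classification and the
evaluation module exists precisely to measure their cost on labelled data.

## Engagement prediction from keyword history

The package predicts a draft post's engagement from history: each
dictionary keyword's historical value is the mean engagement score of past
posts whose text contains it; the prediction is the unweighted mean of the
matched keywords' historical values, falling back to the history-wide mean
when no keyword matches (or none was ever seen). The idea — keywords that
engaged before will engage again — admits many formulas; the unweighted
mean over distinct matched keywords is the simplest rule consistent with
it, and `method = "occurrence"` provides the occurrence-weighted
alternative. Contributions are returned per keyword for explainability.
This is a descriptive heuristic, not a fitted model; it is
translation-consistent (shifting all historical engagements by a constant
shifts every prediction by the same constant), which the tests verify.

## Heat maps and word frequencies

`engagement_heatmap()` bins posts by ISO weekday (1 = Monday) and hour of
the corpus's local timezone — naive timestamps are assumed to be in
`America/Sao_Paulo` by default, since wall-clock posting time is what a
page administrator schedules against. All 168 cells are always present;
empty cells have `NA` mean engagement. The cell shade statistic is mean
engagement by default (configurable to total): the mean answers "when do
posts perform best", the total conflates performance with posting volume.

`word_frequencies()` uses the classifier's tokenizer, removes stopwords
(a shipped Portuguese function-word list, fully overridable) and counts
occurrences corpus-wide; it is the data behind a word-cloud rendering.

## Evaluation against manual labels

`evaluate_assignments()` compares automatic assignments with manual
content-analysis labels: an error is any disagreement, `UNCATEGORIZED` is
its own column on the assigned axis, and the report carries the confusion
matrix, accuracy/error rate and a per-assigned-category breakdown (posts
analyzed, share of posts, errors, share of total errors). Error-rate
percentages are reported at full precision and displayed half-up at one
decimal; the error-share column is `NA` when there are no errors at all,
since 0/0 shares are meaningless.

## The synthetic generator

`generate_corpus()` emulates the *structure* of a one-month crawl of pages
in this domain: per post a true category, a short text, over-dispersed
interaction counts, and a timestamp uniform in a window. Texts mix three
pools — the true category's keywords (fraction `keyword_density`, default
0.3), other categories' keywords (fraction `cross_noise` of the keyword
tokens, default 0) and deterministic pseudo-word filler guaranteed absent
from the dictionary. When `keyword_density > 0` each post carries at least
one keyword token. Consequences: with `cross_noise = 0`, 100% label
recovery is a provable property, not a probabilistic one; increasing
`cross_noise` degrades accuracy monotonically, which is how the pipeline's
behaviour in the published tool's ~80%-accuracy regime is exercised
without its unpublished corpus and dictionary.

Counts are negative binomial with per-category means and variance
$\phi\mu$ ($\phi = 2$ by default) — social-media counts are heavy-tailed,
and a Poisson generator would understate that. Default category means are
taken from the informative-pages rows of the published reference table
(`table1_fixture()`), i.e. realistic magnitudes for this domain; texts are
8–25 tokens, the scale of short page posts. Timestamps default to a
one-month window in March–April 2017 (no DST transition in São Paulo
inside it). Everything is a pure function of `seed`, and the caller's RNG
stream is left untouched.

What the generator does **not** emulate: real Portuguese grammar, topic
drift, typos, multi-topic posts, page-level heterogeneity, or any
dependence of engagement on posting time. Passing tests on synthetic
corpora therefore validate the *mechanics* (counting, argmax, arithmetic,
aggregation) and the noise response of the classifier — they do not certify
accuracy on real pages, which depends entirely on dictionary quality.

## Reference-table arithmetic and its limits

`table1_fixture()` encodes the published per-group, per-category table (32
rows, 4 groups × 8 categories) verbatim: post counts and shares, mean
reactions/shares/comments, weighted average engagement. Recomputing the
final column from the printed means reproduces it to one decimal in 20 of
the 27 non-empty rows; the remaining rows cannot be recovered from the
printed means because the source computed from unrounded per-post data
(and two rows are consistent only with a typo in a printed mean). The
tests pin the arithmetic on the self-consistent rows and the acceptance
suite documents the full sweep honestly.

## Problem sizes and numerical choices

The test suite works at deliberately small scales — corpora of 40–1,000
posts for behavioural properties, 10,000 for generator-mean convergence
(relative error under 5%), 5 seeds × 200 posts per point for the
noise-degradation curve — sizes at which every property checked is already
stable. Tolerances: linearity of the score is checked at $10^{-9}$
relative; chance-level evaluation at 4 Monte-Carlo sigma; heat-map
uniformity against a simultaneous 99% binomial band. Tie-breaks, rounding
and `NA` conventions are as described above, and every one of them is
exercised by a dedicated test rather than assumed.
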