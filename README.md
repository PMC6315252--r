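# postengage

Content classification and engagement analytics for social-media page
posts, built for health-communication research on Facebook pages — the
setting it was designed around is Brazilian cancer-related pages, where
page administrators want to know *which kinds of content* their audience
actually engages with, and whether the topics they post most are the
topics that work.

The package implements the full analysis pipeline:

* a **keyword-dictionary multiclass classifier** that tags each post with a
  content category (testimonies, solidarity, anniversaries, science and
  health, events, institutional, risk factors, beauty — or any user-defined
  scheme) by counting complete-word keyword matches;
* a **weighted engagement score** per post,

  `E = clicks + 0.05 · reactions + 0.2 · shares + 0.75 · comments`

  with the clicks term dropped when only public metrics are available, and
  an **engagement rate** `E / reach` when reach is known. The weights encode
  the effort hierarchy of interactions: reacting < sharing < commenting;
* per-group, per-category **summary tables and rankings** (post counts,
  shares, mean interactions, weighted average engagement);
* **engagement prediction** for a draft post from the engagement history of
  the keywords it uses;
* **weekday × hour heat maps** of posting-time engagement and
  **word-frequency tables** (word-cloud data);
* an **evaluation harness** (accuracy, error rate, confusion matrix,
  per-category error breakdown) against manual content-analysis labels;
* a **synthetic corpus generator** with controllable keyword signal,
  cross-category noise and over-dispersed engagement counts, so the whole
  pipeline is testable without any page export;
* a **command-line interface** (`classify`, `summarize`, `rank`, `predict`,
  `heatmap`, `wordcloud`, `evaluate`, `synth`) over CSV/JSON post tables
  and JSON/YAML dictionaries.

## Worked example

```r
library(postengage)

dict   <- demo_dictionary()                     # shipped 8-category demo dictionary
corpus <- generate_corpus(generator_config(300, dict = dict,
                                           cross_noise = 0.25, seed = 42))

assign <- classify_corpus(corpus, dict)
report <- evaluate_assignments(assign, corpus)  # true labels travel in the corpus
report
#> <evaluation_report> 300 posts, 22 errors: error rate 7.3%, accuracy 92.7%

smry <- summarize_engagement(corpus, assign)
rank_categories(smry)[1:3, c("rank", "category", "weighted_avg_engagement")]
#>   rank                         category weighted_avg_engagement
#> 1    1                    anniversaries               243.59839
#> 2    2 testimonies_or_real_life_stories               194.48171
#> 3    3                       solidarity               142.81915

predict_engagement("pesquisa aponta novo tratamento", corpus, dict)
#> <engagement_prediction> 24.64
#>     keyword           category n_occurrences n_history mean_engagement
#>    pesquisa science_and_health             1        10        31.45000
#>  tratamento science_and_health             1         7        17.82143
```

With 25% of keyword tokens swapped into other categories' pools the
classifier still recovers 92.7% of the generating labels; the ranking shows
that commemorative and testimony posts dominate engagement in this corpus
(their configured means follow the published informative-pages reference
table); and the prediction for the draft text averages the historical mean
engagement of the two science keywords it contains.

The same pipeline from a shell:

```sh
postengage synth    --n 300 --seed 42 --cross-noise 0.25 --out posts.csv --labels labels.csv
postengage classify --posts posts.csv --dict dict.json --out assignments.csv
postengage evaluate --assignments assignments.csv --manual labels.csv --out report.json
```

(the launcher ships at `system.file("cli", "postengage", package = "postengage")`).

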