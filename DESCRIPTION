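Package: postengage
Title: Dictionary-Based Content Classification and Engagement Analytics for Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the content and audience engagement of
    social-media page posts, built around the workflow used for Brazilian
    cancer-communication Facebook pages: a keyword-dictionary multiclass
    post classifier operating on complete normalized word forms, a weighted
    engagement score (clicks + 0.05 reactions + 0.2 shares + 0.75 comments)
    and engagement rate, per-group and per-category engagement summaries and
    rankings, keyword-history engagement prediction, posting-time
    weekday-by-hour heat maps, word-frequency tables, an evaluation harness
    against manual category labels, and a fully reproducible synthetic
    corpus generator for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stringi,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
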