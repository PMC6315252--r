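# Fixtures built in code: a tiny two-category dictionary, a minimal corpus
# builder, and the shipped demonstration dictionary.

tiny_dict <- function() {
  keyword_dictionary(list(
    anniversaries = c("dia", "aniversário", "parabéns"),
    solidarity = c("doador", "doadores", "sangue")
  ))
}

# Build a corpus from defaults; any field can be overridden with a vector.
make_corpus <- function(n = 3, text = "texto qualquer", reactions = 10,
                        shares = 2, comments = 1, clicks = NA, reach = NA,
                        hides = NA, group = "informative",
                        timestamp = "2017-03-20T14:30:00",
                        post_type = "status", manual_category = NA,
                        tz = "America/Sao_Paulo") {
  as_corpus(data.frame(
    post_id = sprintf("p%03d", seq_len(n)),
    page_id = rep_len("page1", n),
    group = rep_len(group, n),
    timestamp = rep_len(timestamp, n),
    post_type = rep_len(post_type, n),
    text = rep_len(text, n),
    reactions = rep_len(reactions, n),
    shares = rep_len(shares, n),
    comments = rep_len(comments, n),
    clicks = rep_len(clicks, n),
    reach = rep_len(reach, n),
    hides = rep_len(hides, n),
    manual_category = rep_len(manual_category, n),
    stringsAsFactors = FALSE
  ), tz = tz)
}

# A corpus whose engagement scores are exactly the given values, via
# shares = 5 * engagement (weight 0.2), everything else zero.
corpus_with_engagement <- function(eng, text = "texto") {
  make_corpus(n = length(eng), text = text, reactions = 0,
              shares = 5 * eng, comments = 0)
}
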