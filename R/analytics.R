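# Posting-time heat map and word-frequency aggregations.
#
# The heat map answers "when does this page's audience engage?": posts are
# binned by local weekday and hour of publication and each of the 168 cells
# aggregates engagement. The word-frequency table is the data behind a word
# cloud: occurrence counts of normalized tokens across all post texts after
# stopword removal.

#' Weekday-by-hour engagement heat map
#'
#' Bins each post by the ISO weekday (1 = Monday ... 7 = Sunday) and hour
#' (0-23) of its timestamp in the corpus timezone, and aggregates engagement
#' per cell. All 168 cells are always present; cells with no post have `NA`
#' mean engagement, never 0.
#'
#' @param corpus A corpus.
#' @param scores Optional [score_posts()] data.frame covering the corpus;
#'   computed from `weights` when omitted.
#' @param weights An [engagement_weights()], used when `scores` is `NULL`.
#' @param aggregate Which statistic the `fill` column carries: `"mean"`
#'   engagement per post (default) or `"total"` engagement.
#' @return A data.frame of class `engagement_heatmap` with 168 rows:
#'   `weekday`, `hour`, `n_posts`, `total_engagement`, `mean_engagement`,
#'   `fill`.
#' @export
engagement_heatmap <- function(corpus, scores = NULL,
                               weights = engagement_weights(),
                               aggregate = c("mean", "total")) {
  stopifnot(inherits(corpus, "corpus"))
  aggregate <- match.arg(aggregate)
  if (is.null(scores)) scores <- score_posts(corpus, weights)
  if (!all(corpus$post_id %in% scores$post_id)) {
    stop("scores do not cover the corpus", call. = FALSE)
  }
  eng <- scores$engagement[match(corpus$post_id, scores$post_id)]

  tz <- attr(corpus, "tz") %||% "America/Sao_Paulo"
  lt <- as.POSIXlt(corpus$timestamp, tz = tz)
  wday <- ifelse(lt$wday == 0, 7L, lt$wday)  # ISO: Monday = 1
  hour <- lt$hour

  grid <- expand.grid(weekday = 1:7, hour = 0:23)
  grid <- grid[order(grid$weekday, grid$hour), ]
  key <- paste(wday, hour)
  gkey <- paste(grid$weekday, grid$hour)
  grid$n_posts <- as.integer(table(factor(key, levels = gkey)))
  tot <- tapply(eng, factor(key, levels = gkey), sum)
  grid$total_engagement <- ifelse(is.na(tot), 0, as.numeric(tot))
  grid$mean_engagement <- ifelse(grid$n_posts > 0,
                                 grid$total_engagement / grid$n_posts,
                                 NA_real_)
  grid$fill <- if (aggregate == "mean") grid$mean_engagement else
    grid$total_engagement
  rownames(grid) <- NULL
  structure(grid, aggregate = aggregate, tz = tz,
            class = c("engagement_heatmap", "data.frame"))
}

#' @export
print.engagement_heatmap <- function(x, ...) {
  cat(sprintf("<engagement_heatmap> %d posts over %d non-empty cells (%s, %s)\n",
              sum(x$n_posts), sum(x$n_posts > 0), attr(x, "aggregate"),
              attr(x, "tz")))
  occupied <- x[x$n_posts > 0, , drop = FALSE]
  if (nrow(occupied) > 0) {
    top <- occupied[order(-occupied$fill), , drop = FALSE]
    print(utils::head(as.data.frame(top), 5), row.names = FALSE)
  }
  invisible(x)
}

#' Plot an engagement heat map
#'
#' Base-graphics rendering: darker cells indicate greater engagement.
#'
#' @param x An [engagement_heatmap()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.engagement_heatmap <- function(x, ...) {
  m <- matrix(x$fill[order(x$weekday, x$hour)], nrow = 24, ncol = 7)
  graphics::image(x = 0:23, y = 1:7, z = m,
                  col = grDevices::grey.colors(64, start = 0.95, end = 0.05),
                  xlab = "hour", ylab = "ISO weekday (1 = Mon)", ...)
  invisible(x)
}

#' Word-frequency table (word-cloud data)
#'
#' Tokenizes all post texts with the classifier's tokenizer, removes
#' stopwords, and counts occurrences across the corpus. Bigger counts mean
#' bigger font in a word-cloud rendering.
#'
#' @param corpus A corpus (or any object with a `text` character column).
#' @param stopwords Character vector of stopwords (normalized internally);
#'   defaults to the shipped Portuguese function-word list, see
#'   [default_stopwords()]. Pass `character()` to keep everything.
#' @return A data.frame of class `word_frequencies` with columns `word` and
#'   `count`, sorted by decreasing count then alphabetically.
#' @examples
#' d <- data.frame(post_id = "p", page_id = "pg", group = "informative",
#'                 timestamp = "2017-04-01T10:00:00", post_type = "status",
#'                 text = "dia dia festa", reactions = 0, shares = 0,
#'                 comments = 0)
#' word_frequencies(as_corpus(d), stopwords = character())
#' @export
word_frequencies <- function(corpus, stopwords = default_stopwords()) {
  tokens <- unlist(tokenize(corpus$text), use.names = FALSE)
  tokens <- tokens[!tokens %in% normalize_word(stopwords)]
  if (length(tokens) == 0) {
    return(structure(data.frame(word = character(), count = integer(),
                                stringsAsFactors = FALSE),
                     class = c("word_frequencies", "data.frame")))
  }
  tab <- table(tokens)
  out <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$word, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("word_frequencies", "data.frame"))
}

#' Default Portuguese stopword list
#'
#' Function words (articles, prepositions, pronouns, common verb forms)
#' suppressed from word-frequency tables; shipped as a plain-text file and
#' overridable via [load_stopwords()] or the `stopwords` argument.
#'
#' @return Character vector of normalized stopwords.
#' @export
default_stopwords <- function() {
  load_stopwords(system.file("extdata", "stopwords_pt.txt",
                             package = "postengage", mustWork = TRUE))
}

#' Load a stopword list from a plain-text file (one word per line)
#'
#' @param path File path; blank lines and `#` comments are ignored.
#' @return Character vector of normalized words.
#' @export
load_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_word(lines))
}
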