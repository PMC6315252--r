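# Synthetic labeled corpora.
#
# The generator emulates the structure of a one-month crawl of Brazilian
# cancer pages: each post gets a true category, a short keyword-bearing
# text, over-dispersed interaction counts whose means depend on the
# category, and a timestamp in a window. Texts are built from three pools:
# the true category's keywords, other categories' keywords (cross-category
# noise), and deterministic pseudo-word filler guaranteed absent from the
# dictionary -- so with zero noise, perfect label recovery is a theorem, not
# a probabilistic hope.

#' Configuration for the synthetic corpus generator
#'
#' @param n_posts Number of posts.
#' @param dict A [keyword_dictionary()]; categories are sampled from its
#'   names. Defaults to the shipped [demo_dictionary()].
#' @param words_per_post Integer range (length 2) of tokens per text;
#'   default 8-25, typical of short page posts.
#' @param keyword_density Fraction of tokens drawn from keyword pools
#'   (default 0.3); the rest is non-dictionary filler. When positive, every
#'   post is guaranteed at least one keyword token, so that with zero
#'   cross-noise every post is classifiable into its true category.
#' @param cross_noise Fraction of the keyword tokens drawn from OTHER
#'   categories' pools instead of the true one (default 0).
#' @param engagement_model Data.frame with columns `category`,
#'   `mean_reactions`, `mean_shares`, `mean_comments`; defaults to the
#'   informative-group reference means ([table1_fixture()]) for categories
#'   present there, and (100, 20, 5) otherwise.
#' @param dispersion Variance multiplier for the negative-binomial counts
#'   (variance = dispersion x mean, default 2): social-media counts are
#'   heavy-tailed.
#' @param timestamp_window Length-2 POSIXct/character window for uniform
#'   timestamps; default the month 2017-03-14 to 2017-04-14.
#' @param group Page-group label stamped on the posts (default
#'   `"informative"`).
#' @param page_id Page id stamped on the posts.
#' @param seed Integer seed; fully determines the corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_posts, dict = demo_dictionary(),
                             words_per_post = c(8L, 25L),
                             keyword_density = 0.3, cross_noise = 0,
                             engagement_model = NULL, dispersion = 2,
                             timestamp_window = c("2017-03-14T00:00:00",
                                                  "2017-04-14T23:59:59"),
                             group = "informative",
                             page_id = "synthetic_page", seed = 1L) {
  stopifnot(inherits(dict, "keyword_dictionary"),
            n_posts >= 0, length(words_per_post) == 2,
            words_per_post[1] >= 1, words_per_post[2] >= words_per_post[1],
            keyword_density >= 0, keyword_density <= 1,
            cross_noise >= 0, cross_noise <= 1, dispersion > 1)
  if (is.null(engagement_model)) {
    engagement_model <- default_engagement_model(names(dict))
  }
  need <- c("category", "mean_reactions", "mean_shares", "mean_comments")
  if (!all(need %in% names(engagement_model)) ||
      !all(names(dict) %in% engagement_model$category)) {
    stop("engagement_model must give mean counts for every dictionary category",
         call. = FALSE)
  }
  structure(list(
    n_posts = as.integer(n_posts), dict = dict,
    words_per_post = as.integer(words_per_post),
    keyword_density = keyword_density, cross_noise = cross_noise,
    engagement_model = engagement_model, dispersion = dispersion,
    timestamp_window = timestamp_window, group = group, page_id = page_id,
    seed = as.integer(seed)), class = "generator_config")
}

default_engagement_model <- function(categories) {
  ref <- table1_fixture()
  ref <- ref[ref$group == "informative" & !is.na(ref$mean_reactions), ]
  idx <- match(categories, ref$category)
  data.frame(
    category = categories,
    mean_reactions = ifelse(is.na(idx), 100, ref$mean_reactions[idx]),
    mean_shares = ifelse(is.na(idx), 20, ref$mean_shares[idx]),
    mean_comments = ifelse(is.na(idx), 5, ref$mean_comments[idx]),
    stringsAsFactors = FALSE)
}

# variance = phi * mu  =>  size = mu / (phi - 1); mu = 0 draws are all 0.
rnbinom_disp <- function(n, mu, phi) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                               size = mu[pos] / (phi - 1))
  }
  out
}

#' Generate a labeled synthetic post corpus
#'
#' Fully reproducible from `config$seed` (the caller's RNG state is left
#' untouched). The true category of every post is written into the
#' `manual_category` column, so the corpus plugs directly into
#' [evaluate_assignments()] as ground truth.
#'
#' @param config A [generator_config()].
#' @return A corpus of `config$n_posts` posts with `manual_category` filled
#'   with the generating labels.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  dict <- config$dict
  cats <- names(dict)
  if (any(lengths(dict) == 0)) {
    stop("cannot generate from a dictionary with an empty category: ",
         paste(cats[lengths(dict) == 0], collapse = ", "), call. = FALSE)
  }
  n <- config$n_posts
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  filler <- filler_vocabulary(dict, size = 400)
  em <- config$engagement_model
  win <- parse_timestamp(as.character(config$timestamp_window),
                         tz = "America/Sao_Paulo")

  true_cat <- if (n > 0) sample(cats, n, replace = TRUE) else character()
  texts <- character(n)
  for (i in seq_len(n)) {
    n_words <- sample(seq(config$words_per_post[1],
                          config$words_per_post[2]), 1)
    is_kw <- stats::runif(n_words) < config$keyword_density
    # every post carries at least one keyword token (when density > 0), so
    # noiseless label recovery is guaranteed rather than merely likely
    if (config$keyword_density > 0 && !any(is_kw)) {
      is_kw[sample.int(n_words, 1)] <- TRUE
    }
    words <- character(n_words)
    if (any(!is_kw)) {
      words[!is_kw] <- sample(filler, sum(!is_kw), replace = TRUE)
    }
    for (j in which(is_kw)) {
      pool_cat <- if (length(cats) > 1 &&
                      stats::runif(1) < config$cross_noise) {
        sample(setdiff(cats, true_cat[i]), 1)
      } else {
        true_cat[i]
      }
      words[j] <- sample(dict[[pool_cat]], 1)
    }
    texts[i] <- paste(words, collapse = " ")
  }

  ei <- match(true_cat, em$category)
  df <- data.frame(
    post_id = sprintf("post_%05d", seq_len(n)),
    page_id = rep(config$page_id, n),
    group = rep(config$group, n),
    timestamp = as.POSIXct(stats::runif(n, as.numeric(win[1]),
                                        as.numeric(win[2])),
                           origin = "1970-01-01", tz = "America/Sao_Paulo"),
    post_type = if (n > 0) sample(post_types(), n, replace = TRUE)
                else character(),
    text = texts,
    reactions = rnbinom_disp(n, em$mean_reactions[ei], config$dispersion),
    shares = rnbinom_disp(n, em$mean_shares[ei], config$dispersion),
    comments = rnbinom_disp(n, em$mean_comments[ei], config$dispersion),
    manual_category = true_cat,
    stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(floor(as.numeric(df$timestamp)),
                             origin = "1970-01-01", tz = "America/Sao_Paulo")
  as_corpus(df, provenance = sprintf("synthetic (seed %d)", config$seed))
}

# Deterministic pseudo-words, filtered against the dictionary so filler can
# never match a keyword.
filler_vocabulary <- function(dict, size = 400) {
  syll <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ru",
            "sa", "te", "vi", "xo", "ze")
  idx <- seq_len(size) - 1
  words <- paste0("zz", syll[(idx %% 15) + 1],
                  syll[((idx %/% 15) %% 15) + 1],
                  syll[((idx %/% 225) %% 15) + 1])
  setdiff(unique(words), unlist(dict, use.names = FALSE))
}

#' Reference per-category engagement table
#'
#' The published per-group, per-category summary of the 712-post, 16-page
#' Brazilian cancer-page study: post counts and shares, mean reactions,
#' shares and comments, and the weighted average engagement, for the four
#' page groups and eight categories (empty cells are `NA`). Useful for
#' regression-testing the engagement arithmetic and as realistic generator
#' means.
#'
#' @return A `category_summaries` data.frame with 32 rows.
#' @export
table1_fixture <- function() {
  g <- function(group, rows) {
    df <- as.data.frame(do.call(rbind, lapply(rows, function(r) r[-1])))
    names(df) <- c("n_posts", "pct_posts", "mean_reactions", "mean_shares",
                   "mean_comments", "weighted_avg_engagement")
    cbind(group = group, category = vapply(rows, `[[`, "", 1), df,
          stringsAsFactors = FALSE)
  }
  r <- function(cat, ...) c(list(cat), list(...))
  hosp <- list(
    r("solidarity", 11, 10, 524, 346.9, 21.4, 111.6),
    r("anniversaries", 0, 0, NA, NA, NA, NA),
    r("institutional", 57, 52.2, 825.1, 161.3, 56.4, 115.8),
    r("testimonies_or_real_life_stories", 2, 1.8, 179, 26.5, 3, 16.4),
    r("science_and_health", 20, 18.3, 1263.3, 440.5, 47, 186.5),
    r("events", 18, 16.5, 283.7, 52.5, 13.8, 35.1),
    r("beauty", 0, 0, NA, NA, NA, NA),
    r("risk_factors", 1, 0.9, 219, 57, 12, 31.3))
  info <- list(
    r("solidarity", 19, 7.3, 1400.7, 227.9, 43, 147.9),
    r("anniversaries", 29, 11.1, 2209.9, 717.4, 27, 274.2),
    r("institutional", 26, 9.9, 397.3, 72.8, 5.7, 38.7),
    r("testimonies_or_real_life_stories", 25, 9.6, 1976.5, 79.9, 108.8, 196.4),
    r("science_and_health", 129, 49.4, 143.4, 50.7, 3.8, 20.1),
    r("events", 28, 10.7, 114.8, 28.4, 30.4, 34.2),
    r("beauty", 1, 0.3, 85, 19, 3, 10.3),
    r("risk_factors", 4, 1.5, 76.2, 26.5, 2.2, 10.8))
  ngo <- list(
    r("solidarity", 76, 48.7, 559.8, 24.3, 16.2, 45.0),
    r("anniversaries", 8, 5.1, 1641, 108.3, 33.8, 129.1),
    r("institutional", 27, 17.3, 620.6, 37.8, 15.7, 50.4),
    r("testimonies_or_real_life_stories", 11, 7.1, 505.8, 24.5, 11.3, 38.7),
    r("science_and_health", 0, 0, NA, NA, NA, NA),
    r("events", 33, 21.1, 305.3, 84.2, 18, 45.6),
    r("beauty", 1, 0.6, 124, 0, 4, 9.2),
    r("risk_factors", 0, 0, NA, NA, NA, NA))
  pers <- list(
    r("solidarity", 53, 28.5, 1885.2, 32.8, 48.9, 135.5),
    r("anniversaries", 9, 4.3, 1320.7, 10.8, 29.7, 90.5),
    r("institutional", 26, 13.9, 340.2, 8.7, 7.4, 24.3),
    r("testimonies_or_real_life_stories", 68, 36.6, 236.6, 18.4, 26.7, 35.6),
    r("science_and_health", 0, 0, NA, NA, NA, NA),
    r("events", 10, 5.3, 401.6, 8.8, 11.6, 30.5),
    r("beauty", 19, 10.2, 149.7, 8.3, 5.9, 16.6),
    r("risk_factors", 1, 0.5, 20, 1, 2, 2.7))
  out <- rbind(g("hospitals_or_foundations", hosp), g("informative", info),
               g("ngo", ngo), g("personal", pers))
  num <- setdiff(names(out), c("group", "category"))
  out[num] <- lapply(out[num], function(v) as.numeric(unlist(v)))
  rownames(out) <- NULL
  structure(out, class = c("category_summaries", "data.frame"))
}
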