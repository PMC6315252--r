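# Weighted engagement metric, per-category summaries, rankings and
# keyword-history prediction.
#
# The engagement score per post is
#   clicks + 0.05 * reactions + 0.2 * shares + 0.75 * comments
# with the clicks term dropped when click data are unavailable (public-data
# mode). The weights encode an effort hierarchy: reacting is the cheapest
# interaction, sharing means the user identifies with the content, and
# commenting demands drafting text and taking a public position, so it
# weighs most. The engagement rate divides the score by reach (unique
# viewers) and is undefined -- not zero -- when reach is absent or zero.

#' Engagement weights
#'
#' @param reactions Weight for reactions (default 0.05).
#' @param shares Weight for shares (default 0.2).
#' @param comments Weight for comments (default 0.75).
#' @param include_clicks Should clicks enter the score (weight 1) when
#'   present? Default `TRUE`; public-data analyses set this to `FALSE` or
#'   simply have no clicks column.
#' @return An `engagement_weights` object.
#' @export
engagement_weights <- function(reactions = 0.05, shares = 0.2,
                               comments = 0.75, include_clicks = TRUE) {
  w <- c(reactions = reactions, shares = shares, comments = comments)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  structure(list(reactions = reactions, shares = shares, comments = comments,
                 include_clicks = isTRUE(include_clicks)),
            class = "engagement_weights")
}

#' Weighted engagement score from interaction counts
#'
#' The core formula, vectorized. `clicks` may be `NA` (treated as an absent
#' clicks term, i.e. 0) -- this is what allows scoring posts for which only
#' the public metrics exist.
#'
#' @param reactions,shares,comments Non-negative numeric vectors (counts or
#'   mean counts; the formula is linear so both make sense).
#' @param clicks Optional numeric vector; `NA` or `NULL` contributes 0.
#' @param weights An [engagement_weights()].
#' @return Numeric vector of engagement scores.
#' @examples
#' weighted_engagement(524, 346.9, 21.4) # 111.63
#' @export
weighted_engagement <- function(reactions, shares, comments, clicks = NULL,
                                weights = engagement_weights()) {
  stopifnot(inherits(weights, "engagement_weights"))
  base <- weights$reactions * reactions + weights$shares * shares +
    weights$comments * comments
  if (!is.null(clicks) && weights$include_clicks) {
    base <- base + ifelse(is.na(clicks), 0, clicks)
  }
  base
}

#' Score every post of a corpus
#'
#' @param corpus A corpus.
#' @param weights An [engagement_weights()].
#' @return A data.frame `post_id`, `engagement`, `engagement_rate`; the rate
#'   is `NA` whenever reach is absent or zero.
#' @export
score_posts <- function(corpus, weights = engagement_weights()) {
  stopifnot(inherits(corpus, "corpus"))
  eng <- weighted_engagement(corpus$reactions, corpus$shares,
                             corpus$comments, corpus$clicks, weights)
  rate <- ifelse(!is.na(corpus$reach) & corpus$reach > 0,
                 eng / corpus$reach, NA_real_)
  data.frame(post_id = corpus$post_id, engagement = eng,
             engagement_rate = rate, stringsAsFactors = FALSE)
}

#' Per-group, per-category engagement summary
#'
#' For each (page group, category) cell: number of posts, percentage of the
#' group's posts, arithmetic means of reactions/shares/comments, and the
#' weighted average engagement computed from those means. Because the score
#' is linear in the counts, the score of the means equals the mean of the
#' per-post scores. Categories present in the scheme but empty in a group
#' are reported with `NA` means. Clicks enter only when `weights$include_clicks`
#' is `TRUE` and every post in the corpus has a clicks value; the reference
#' analysis uses public metrics only, where clicks are unavailable.
#'
#' @param corpus A corpus.
#' @param assignments A [classify_corpus()] result covering the corpus (or
#'   any data.frame with `post_id` and `assigned_category`).
#' @param weights An [engagement_weights()].
#' @param categories Category scheme for the rows; defaults to the
#'   assignment's dictionary categories plus [uncategorized_label()] when
#'   any post is uncategorized.
#' @return A data.frame of class `category_summaries` with columns `group`,
#'   `category`, `n_posts`, `pct_posts`, `mean_reactions`, `mean_shares`,
#'   `mean_comments`, `weighted_avg_engagement`. Percentages are rounded
#'   half-up to 1 decimal; means and engagement are full precision.
#' @export
summarize_engagement <- function(corpus, assignments,
                                 weights = engagement_weights(),
                                 categories = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  if (!all(c("post_id", "assigned_category") %in% names(assignments))) {
    stop("assignments must have post_id and assigned_category", call. = FALSE)
  }
  unknown <- setdiff(assignments$post_id, corpus$post_id)
  if (length(unknown) > 0) {
    stop("assignment references unknown post_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_assign <- setdiff(corpus$post_id, assignments$post_id)
  if (length(missing_assign) > 0) {
    stop("no assignment for post_id: ",
         paste(missing_assign, collapse = ", "), call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- attr(assignments, "categories") %||%
      setdiff(unique(assignments$assigned_category), uncategorized_label())
    if (uncategorized_label() %in% assignments$assigned_category) {
      categories <- c(categories, uncategorized_label())
    }
  }
  cat_of <- assignments$assigned_category[match(corpus$post_id,
                                                assignments$post_id)]
  use_clicks <- weights$include_clicks && !anyNA(corpus$clicks)

  res <- list()
  for (g in unique(corpus$group)) {
    in_g <- corpus$group == g
    n_g <- sum(in_g)
    for (cat_name in categories) {
      sel <- in_g & cat_of == cat_name
      n <- sum(sel)
      if (n == 0) {
        mr <- ms <- mc <- eng <- NA_real_
      } else {
        mr <- mean(corpus$reactions[sel])
        ms <- mean(corpus$shares[sel])
        mc <- mean(corpus$comments[sel])
        mk <- if (use_clicks) mean(corpus$clicks[sel]) else NULL
        eng <- weighted_engagement(mr, ms, mc, mk, weights)
      }
      res[[length(res) + 1]] <- data.frame(
        group = g, category = cat_name, n_posts = n,
        pct_posts = round_half_up(100 * n / n_g, 1),
        mean_reactions = mr, mean_shares = ms, mean_comments = mc,
        weighted_avg_engagement = eng, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("category_summaries", "data.frame"))
}

#' Rank categories by a summary metric
#'
#' Descending order of the chosen metric; `NA` entries (empty categories)
#' sort last; ties break alphabetically by category name. A `rank` column
#' is added (NA rows carry `NA` rank).
#'
#' @param summaries A [summarize_engagement()] result (or the
#'   [table1_fixture()] reference table), typically filtered to one group.
#' @param metric Name of a numeric summary column, e.g.
#'   `"weighted_avg_engagement"` (default), `"mean_reactions"`, `"n_posts"`.
#' @return `summaries` reordered, with a `rank` column prepended.
#' @export
rank_categories <- function(summaries, metric = "weighted_avg_engagement") {
  if (!metric %in% names(summaries) || !is.numeric(summaries[[metric]])) {
    stop("unknown or non-numeric metric: ", metric, call. = FALSE)
  }
  v <- summaries[[metric]]
  ord <- order(-v, summaries$category, na.last = TRUE, method = "radix")
  out <- summaries[ord, , drop = FALSE]
  out <- cbind(rank = ifelse(is.na(out[[metric]]), NA_integer_,
                             seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Predict the engagement of a new post text from keyword history
#'
#' Rule: a keyword that generated high engagement in past posts makes high
#' engagement likelier for new posts using it. Concretely, each dictionary
#' keyword's historical value is the mean engagement score of the past posts
#' whose text contains it; the prediction for a new text is the mean of its
#' matched keywords' historical values (occurrence-weighted if
#' `method = "occurrence"`). A text matching no keyword falls back to the
#' history-wide mean engagement. Keywords never seen in the history are
#' skipped (they carry no evidence).
#'
#' @param text New post text.
#' @param history A corpus of past posts (non-empty).
#' @param dict A `keyword_dictionary`.
#' @param weights An [engagement_weights()].
#' @param method `"keyword_mean"` (default): unweighted mean over the
#'   distinct matched keywords; `"occurrence"`: keywords weighted by their
#'   occurrence count in `text`.
#' @return A list of class `engagement_prediction`: `prediction`,
#'   `fallback` (TRUE when the corpus mean was used), and `contributions`
#'   (data.frame: keyword, category, n_occurrences in the new text,
#'   n_history posts, historical mean engagement).
#' @export
predict_engagement <- function(text, history, dict,
                               weights = engagement_weights(),
                               method = c("keyword_mean", "occurrence")) {
  stopifnot(inherits(history, "corpus"), inherits(dict, "keyword_dictionary"))
  method <- match.arg(method)
  if (nrow(history) == 0) stop("history is empty", call. = FALSE)

  scores <- score_posts(history, weights)$engagement
  hist_tokens <- tokenize(history$text)
  new_tokens <- tokenize(text)[[1]]

  all_kw <- unlist(unclass(dict), use.names = FALSE)
  kw_cat <- rep(names(dict), lengths(dict))
  matched <- new_tokens[new_tokens %in% all_kw]

  if (length(matched) == 0) {
    return(structure(list(
      prediction = mean(scores), fallback = TRUE,
      contributions = data.frame(keyword = character(), category = character(),
                                 n_occurrences = integer(),
                                 n_history = integer(),
                                 mean_engagement = numeric(),
                                 stringsAsFactors = FALSE)),
      class = "engagement_prediction"))
  }

  occ <- table(matched)
  kws <- names(occ)
  contrib <- data.frame(
    keyword = kws,
    category = kw_cat[match(kws, all_kw)],
    n_occurrences = as.integer(occ),
    n_history = NA_integer_, mean_engagement = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_along(kws)) {
    has_kw <- vapply(hist_tokens, function(tk) kws[i] %in% tk, logical(1))
    contrib$n_history[i] <- sum(has_kw)
    if (any(has_kw)) contrib$mean_engagement[i] <- mean(scores[has_kw])
  }
  seen <- !is.na(contrib$mean_engagement)
  if (!any(seen)) {
    pred <- mean(scores)
    fallback <- TRUE
  } else {
    fallback <- FALSE
    pred <- if (method == "keyword_mean") {
      mean(contrib$mean_engagement[seen])
    } else {
      stats::weighted.mean(contrib$mean_engagement[seen],
                           contrib$n_occurrences[seen])
    }
  }
  structure(list(prediction = pred, fallback = fallback,
                 contributions = contrib),
            class = "engagement_prediction")
}

#' @export
print.engagement_prediction <- function(x, ...) {
  cat(sprintf("<engagement_prediction> %.2f%s\n", x$prediction,
              if (x$fallback) " (fallback: history-wide mean)" else ""))
  if (nrow(x$contributions) > 0) print(x$contributions, row.names = FALSE)
  invisible(x)
}

#' @export
print.category_summaries <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round_half_up(v, 1))
  print(df, row.names = FALSE)
  invisible(x)
}
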