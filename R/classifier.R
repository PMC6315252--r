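# Keyword-count post classifier.
#
# Each post is tokenized into complete normalized words; the post is assigned
# to the category whose keyword set matches the highest number of token
# OCCURRENCES (a keyword appearing twice counts twice). Ties are broken
# deterministically and flagged; a post matching no keyword at all is
# labelled UNCATEGORIZED rather than forced into a category. There is no
# context, negation, typo or compound-word handling: the matcher only reads
# complete words.

#' Count keyword matches per category
#'
#' @param tokens Character vector of normalized tokens (from [tokenize()]).
#' @param dict A [keyword_dictionary()].
#' @return Named integer vector, one entry per dictionary category (0 when
#'   nothing matches): the number of token occurrences belonging to each
#'   category's keyword set.
#' @examples
#' d <- keyword_dictionary(list(anniversaries = "dia", solidarity = "doador"))
#' count_matches(c("dia", "das", "mães", "dia"), d)
#' @export
count_matches <- function(tokens, dict) {
  stopifnot(inherits(dict, "keyword_dictionary"))
  vapply(dict, function(words) sum(tokens %in% words), integer(1))
}

#' Classify one post text
#'
#' Assigns the category with the strictly highest keyword-occurrence count.
#' When two or more categories tie for the maximum, the tie is resolved
#' deterministically (`tie_break`) and flagged so reports can surface the
#' ambiguity. When no keyword matches, the post gets the
#' [uncategorized_label()].
#'
#' @param text A single post text (or an element of a corpus `text` column).
#' @param dict A `keyword_dictionary`.
#' @param tie_break Either `"alpha"` (default: the tied category first in
#'   alphabetical order wins) or a character vector of category names used
#'   as a priority list.
#' @return A list of class `category_assignment`: `assigned_category`,
#'   `tie` (logical), `counts` (named integer vector) and
#'   `matched_keywords` (per category, the matched token occurrences).
#' @examples
#' d <- keyword_dictionary(list(anniversaries = "dia", solidarity = "doador"))
#' classify("Hoje é dia de festa, dia especial", d)
#' @export
classify <- function(text, dict, tie_break = "alpha") {
  tokens <- tokenize(text)[[1]]
  counts <- count_matches(tokens, dict)
  matched <- lapply(dict, function(words) tokens[tokens %in% words])
  top <- max(counts, 0L)
  if (top == 0L) {
    assigned <- uncategorized_label()
    tie <- FALSE
  } else {
    winners <- names(counts)[counts == top]
    tie <- length(winners) > 1
    assigned <- break_tie(winners, tie_break)
  }
  structure(
    list(assigned_category = assigned, tie = tie, counts = counts,
         matched_keywords = matched),
    class = "category_assignment"
  )
}

break_tie <- function(winners, tie_break) {
  if (identical(tie_break, "alpha")) {
    return(sort(winners, method = "radix")[1])
  }
  if (is.character(tie_break) && length(tie_break) >= 1) {
    hit <- tie_break[tie_break %in% winners]
    if (length(hit) > 0) return(hit[1])
    return(sort(winners, method = "radix")[1])
  }
  stop("tie_break must be \"alpha\" or a character priority list",
       call. = FALSE)
}

#' Classify every post of a corpus
#'
#' Stateless per post: an assignment never depends on the other posts, so a
#' permuted corpus yields identically permuted assignments.
#'
#' @param corpus A [as_corpus()] corpus.
#' @param dict A `keyword_dictionary`.
#' @inheritParams classify
#' @return A data.frame of class `category_assignments`: columns `post_id`,
#'   `assigned_category`, `tie`, then one `n_<category>` count column per
#'   dictionary category.
#' @export
classify_corpus <- function(corpus, dict, tie_break = "alpha") {
  stopifnot(inherits(corpus, "corpus"), inherits(dict, "keyword_dictionary"))
  n <- nrow(corpus)
  cats <- names(dict)
  counts <- matrix(0L, nrow = n, ncol = length(cats),
                   dimnames = list(NULL, cats))
  assigned <- character(n)
  tie <- logical(n)
  token_list <- tokenize(corpus$text)
  for (i in seq_len(n)) {
    cts <- count_matches(token_list[[i]], dict)
    counts[i, ] <- cts
    top <- max(cts, 0L)
    if (top == 0L) {
      assigned[i] <- uncategorized_label()
    } else {
      winners <- cats[cts == top]
      tie[i] <- length(winners) > 1
      assigned[i] <- break_tie(winners, tie_break)
    }
  }
  out <- data.frame(post_id = corpus$post_id, assigned_category = assigned,
                    tie = tie, stringsAsFactors = FALSE)
  count_df <- as.data.frame(counts)
  names(count_df) <- paste0("n_", cats)
  out <- cbind(out, count_df)
  structure(out, categories = cats,
            class = c("category_assignments", "data.frame"))
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("<category_assignment> %s%s\n", x$assigned_category,
              if (x$tie) " (tie)" else ""))
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0) {
    for (cat_name in names(nz)) {
      cat(sprintf("  %s: %d (%s)\n", cat_name, nz[[cat_name]],
                  paste(x$matched_keywords[[cat_name]], collapse = ", ")))
    }
  } else {
    cat("  no keyword matched\n")
  }
  invisible(x)
}
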