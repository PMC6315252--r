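# Evaluation of automatic assignments against manual content-analysis
# labels: accuracy, error rate, confusion matrix and per-category error
# breakdown. An error is simply assigned != manual;
# UNCATEGORIZED is treated as a category of its own on the assigned axis.

#' Compare automatic assignments with manual labels
#'
#' @param assignments A [classify_corpus()] result (or any data.frame with
#'   `post_id` and `assigned_category`).
#' @param manual Either a named character vector (`post_id` -> category), a
#'   data.frame with `post_id` and `manual_category` columns, or a corpus
#'   whose `manual_category` column is filled. Every assigned post must have
#'   a manual label.
#' @return An `evaluation_report`: list with `n_posts`, `n_errors`,
#'   `error_rate` (percent, full precision), `accuracy` (= 100 - error
#'   rate), `confusion` (matrix, manual labels in rows, assigned in
#'   columns), and `per_category` (see [error_breakdown()]).
#' @examples
#' a <- data.frame(post_id = c("1", "2"), assigned_category = c("a", "b"))
#' evaluate_assignments(a, c(`1` = "a", `2` = "a"))
#' @export
evaluate_assignments <- function(assignments, manual) {
  if (!all(c("post_id", "assigned_category") %in% names(assignments))) {
    stop("assignments must have post_id and assigned_category", call. = FALSE)
  }
  if (is.data.frame(manual)) {
    lab_col <- if ("manual_category" %in% names(manual)) "manual_category"
               else "category"
    if (!all(c("post_id", lab_col) %in% names(manual))) {
      stop("manual labels need post_id and manual_category columns",
           call. = FALSE)
    }
    manual <- stats::setNames(as.character(manual[[lab_col]]),
                              manual$post_id)
  }
  ids <- as.character(assignments$post_id)
  lab <- manual[ids]
  missing_lab <- ids[is.na(lab)]
  if (length(missing_lab) > 0) {
    stop("missing manual label for post_id: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  assigned <- as.character(assignments$assigned_category)
  lev <- sort(unique(c(lab, assigned)), method = "radix")
  confusion <- table(manual = factor(lab, levels = lev),
                     assigned = factor(assigned, levels = lev))
  n <- length(ids)
  n_err <- sum(assigned != lab)
  report <- structure(
    list(n_posts = n, n_errors = n_err,
         error_rate = 100 * n_err / n,
         accuracy = 100 - 100 * n_err / n,
         confusion = unclass(confusion),
         per_category = NULL),
    class = "evaluation_report")
  report$per_category <- error_breakdown_impl(assigned, lab)
  report
}

error_breakdown_impl <- function(assigned, lab) {
  cats <- sort(unique(assigned), method = "radix")
  n <- length(assigned)
  n_err <- sum(assigned != lab)
  out <- data.frame(
    category = cats,
    n_assigned = vapply(cats, function(cc) sum(assigned == cc), integer(1)),
    n_errors = vapply(cats, function(cc) sum(assigned == cc & lab != cc),
                      integer(1)),
    stringsAsFactors = FALSE)
  out$pct_of_assigned <- round_half_up(100 * out$n_assigned / n, 1)
  out$pct_of_total_errors <- if (n_err == 0) NA_real_ else
    round_half_up(100 * out$n_errors / n_err, 1)
  out[, c("category", "n_assigned", "pct_of_assigned", "n_errors",
          "pct_of_total_errors")]
}

#' Per-category error breakdown
#'
#' One row per assigned category: how many posts the tool put there, the
#' share of all posts that represents, how many of them disagree with the
#' manual label, and that category's share of all errors. Percentages are
#' rounded half-up to 1 decimal; the error-share column is `NA` throughout
#' when there are no errors at all.
#'
#' @param report An [evaluate_assignments()] report.
#' @return A data.frame with columns `category`, `n_assigned`,
#'   `pct_of_assigned`, `n_errors`, `pct_of_total_errors`.
#' @export
error_breakdown <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  report$per_category
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d posts, %d errors: error rate %.1f%%, accuracy %.1f%%\n",
              x$n_posts, x$n_errors, round_half_up(x$error_rate, 1),
              round_half_up(x$accuracy, 1)))
  cat("per assigned category:\n")
  print(x$per_category, row.names = FALSE)
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  print(object)
  cat("confusion matrix (rows = manual, cols = assigned):\n")
  print(object$confusion)
  invisible(object)
}
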