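# Post corpus container and CSV/JSON interchange.
#
# A corpus is a data.frame with one row per post and a fixed column set; the
# three interaction counts (reactions, shares, comments) are mandatory, the
# administrator-only metrics (clicks, reach, hides) are optional and kept as
# NA when a source does not provide them -- "reach unavailable" and
# "reach = 0" are different things for the engagement rate.

CORPUS_COLUMNS <- c(
  "post_id", "page_id", "group", "timestamp", "post_type", "text",
  "reactions", "shares", "comments", "clicks", "reach", "hides",
  "manual_category"
)
REQUIRED_COLUMNS <- c(
  "post_id", "page_id", "group", "timestamp", "post_type", "text",
  "reactions", "shares", "comments"
)
COUNT_COLUMNS <- c("reactions", "shares", "comments", "clicks", "reach", "hides")

#' Facebook post types
#'
#' The five publication formats a page post can take: photo (any image file),
#' video, event, status (text-only post) and link.
#'
#' @return Character vector of valid `post_type` values.
#' @export
post_types <- function() c("photo", "video", "event", "status", "link")

#' Default page-group labels
#'
#' The four page-profile groups used to organise pages: hospitals or
#' foundations, informative pages, NGOs and personal pages. Free labels are
#' also accepted in a corpus.
#'
#' @return Character vector of the four default group labels.
#' @export
page_groups <- function() {
  c("hospitals_or_foundations", "informative", "ngo", "personal")
}

#' Build a validated post corpus from a data frame
#'
#' Checks the column contract (required columns present, counts non-negative,
#' post types valid, post ids unique), fills absent optional columns with
#' `NA`, parses character timestamps, and returns a `corpus` object.
#'
#' @param x A data.frame with at least the required columns `post_id`,
#'   `page_id`, `group`, `timestamp`, `post_type`, `text`, `reactions`,
#'   `shares`, `comments`. Optional: `clicks`, `reach`, `hides`,
#'   `manual_category`.
#' @param provenance Free-text note on where the posts came from.
#' @param tz Timezone applied to naive timestamps; defaults to
#'   `"America/Sao_Paulo"` (Brazilian pages). Timestamps carrying an explicit
#'   UTC offset are converted into this zone, which is what the posting-time
#'   heat map uses as local wall-clock time.
#' @return A `corpus`: a data.frame with the fixed 13-column layout and
#'   attributes `provenance` and `tz`.
#' @examples
#' df <- data.frame(
#'   post_id = "p1", page_id = "pg", group = "informative",
#'   timestamp = "2017-03-20T14:30:00", post_type = "photo",
#'   text = "Vamos falar sobre prevenção", reactions = 10, shares = 2,
#'   comments = 1
#' )
#' as_corpus(df)
#' @export
as_corpus <- function(x, provenance = "", tz = "America/Sao_Paulo") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(CORPUS_COLUMNS, names(x))) {
    x[[col]] <- rep(if (col %in% COUNT_COLUMNS) NA_real_ else NA_character_,
                    nrow(x))
  }
  x <- x[, CORPUS_COLUMNS, drop = FALSE]

  x$post_id <- as.character(x$post_id)
  x$page_id <- as.character(x$page_id)
  x$group <- as.character(x$group)
  x$post_type <- as.character(x$post_type)
  x$text <- as.character(x$text)
  x$text[is.na(x$text)] <- ""
  x$manual_category <- as.character(x$manual_category)
  x$timestamp <- parse_timestamp(x$timestamp, tz = tz)

  for (col in COUNT_COLUMNS) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
    bad <- !is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] != floor(x[[col]]))
    if (any(bad)) {
      stop("invalid (negative or non-integer) ", col, " for post_id: ",
           paste(x$post_id[bad], collapse = ", "), call. = FALSE)
    }
    if (col %in% c("reactions", "shares", "comments") && anyNA(x[[col]])) {
      stop("missing ", col, " for post_id: ",
           paste(x$post_id[is.na(x[[col]])], collapse = ", "), call. = FALSE)
    }
  }
  bad_type <- !x$post_type %in% post_types()
  if (any(bad_type)) {
    stop("unknown post_type ",
         paste(unique(x$post_type[bad_type]), collapse = ", "),
         " for post_id: ", paste(x$post_id[bad_type], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$post_id)) {
    stop("duplicate post_id: ",
         paste(unique(x$post_id[duplicated(x$post_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x$timestamp)) {
    stop("unparseable timestamp for post_id: ",
         paste(x$post_id[is.na(x$timestamp)], collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, provenance = provenance, tz = tz,
            class = c("corpus", "data.frame"))
}

# ISO 8601, with or without a numeric UTC offset; naive times take `tz`.
parse_timestamp <- function(ts, tz) {
  if (inherits(ts, "POSIXct")) return(as.POSIXct(ts, tz = tz))
  ts <- as.character(ts)
  ts <- sub("Z$", "+0000", ts)
  ts <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", ts)
  out <- as.POSIXct(rep(NA_real_, length(ts)), tz = tz)
  has_offset <- grepl("[+-]\\d{4}$", ts)
  if (any(has_offset)) {
    out[has_offset] <- as.POSIXct(strptime(ts[has_offset],
                                           "%Y-%m-%dT%H:%M:%S%z", tz = tz))
  }
  if (any(!has_offset)) {
    out[!has_offset] <- as.POSIXct(strptime(ts[!has_offset],
                                            "%Y-%m-%dT%H:%M:%S", tz = tz))
  }
  attr(out, "tzone") <- tz
  out
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S%z")

#' Read a post table from CSV or JSON
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @param tz Default timezone for naive timestamps (see [as_corpus()]).
#' @return A validated [as_corpus()] corpus. Optional columns absent from the
#'   file (or empty cells) become `NA`, never 0.
#' @export
read_posts <- function(path, format = c("auto", "csv", "json"),
                       tz = "America/Sao_Paulo") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "",
                          encoding = "UTF-8"),
    json = {
      recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      as.data.frame(recs, stringsAsFactors = FALSE)
    }
  )
  if (nrow(df) > 0 && "text" %in% names(df)) df$text[is.na(df$text)] <- ""
  as_corpus(df, provenance = path, tz = tz)
}

#' Write a post corpus to CSV or JSON
#'
#' The output round-trips through [read_posts()] field-for-field. CSV is
#' UTF-8, comma-separated, header row mandatory, text quoted; absent optional
#' counts are written as empty cells (CSV) or omitted keys (JSON), not as 0.
#'
#' @param corpus A corpus.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_posts <- function(corpus, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(corpus, "corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- as.data.frame(corpus, stringsAsFactors = FALSE)
  out$timestamp <- format_timestamp(out$timestamp)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8", quote = which(
                       vapply(out, is.character, logical(1))))
  } else {
    recs <- lapply(seq_len(nrow(out)), function(i) {
      rec <- as.list(out[i, , drop = FALSE])
      rec[!vapply(rec, function(v) is.na(v[1]), logical(1))]
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d posts, %d page(s), %d group(s)\n",
              nrow(x), length(unique(x$page_id)), length(unique(x$group))))
  if (nrow(x) > 0) {
    cat(sprintf("  period: %s .. %s (%s)\n",
                format(min(x$timestamp)), format(max(x$timestamp)),
                attr(x, "tz")))
  }
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subsetting a corpus keeps its class and attributes when all columns survive.
#' @export
`[.corpus` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(CORPUS_COLUMNS %in% names(out))) {
    attr(out, "provenance") <- attr(x, "provenance")
    attr(out, "tz") <- attr(x, "tz")
    class(out) <- c("corpus", "data.frame")
  }
  out
}
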