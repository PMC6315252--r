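# Category -> keyword dictionary.
#
# Classification is driven by a user-editable mapping from category names to
# sets of complete word forms. The invariants the matcher depends on:
# every keyword is one single word in normalized form, and no word belongs
# to more than one category. Inflections (singular/plural,
# masculine/feminine) are enumerated explicitly -- there is no stemming and
# no root matching, so "doador" does not match "doadores" unless both are
# listed.

#' Default content-analysis category scheme
#'
#' The eight categories used for cancer-page content coding: testimonies or
#' real-life stories, solidarity (donation appeals), anniversaries
#' (commemorative dates), science and health, events, institutional,
#' risk factors, and beauty. User schemes may add or remove categories.
#'
#' @return Character vector of the eight category names.
#' @export
default_categories <- function() {
  c("testimonies_or_real_life_stories", "solidarity", "anniversaries",
    "science_and_health", "events", "institutional", "risk_factors", "beauty")
}

#' Label used for posts matching no dictionary keyword
#' @return The string `"UNCATEGORIZED"`.
#' @export
uncategorized_label <- function() "UNCATEGORIZED"

#' Construct a keyword dictionary
#'
#' @param keywords Named list: category name -> character vector of single
#'   word forms. Words are normalized (NFC, lowercased, diacritics kept) and
#'   deduplicated within a category.
#' @param generic_words Optional character vector of words considered too
#'   generic to discriminate between categories (e.g. "câncer"); their
#'   presence in the dictionary triggers a warning, not an error -- excluding
#'   them is the dictionary author's call.
#' @return A `keyword_dictionary` object (named list of normalized keyword
#'   vectors, category order preserved).
#' @examples
#' keyword_dictionary(list(
#'   solidarity = c("doador", "doadores"),
#'   anniversaries = c("dia", "aniversário")
#' ))
#' @export
keyword_dictionary <- function(keywords, generic_words = NULL) {
  if (!is.list(keywords) || is.null(names(keywords)) ||
      any(!nzchar(names(keywords)))) {
    stop("keywords must be a named list of category -> word vectors",
         call. = FALSE)
  }
  if (anyDuplicated(names(keywords))) {
    stop("duplicate category name: ",
         paste(unique(names(keywords)[duplicated(names(keywords))]),
               collapse = ", "), call. = FALSE)
  }
  dict <- lapply(keywords, function(words) {
    words <- normalize_word(as.character(words))
    multi <- grepl("\\s", words)
    if (any(multi)) {
      stop("keywords must be single complete words, got: ",
           paste(words[multi], collapse = ", "), call. = FALSE)
    }
    sort(unique(words[nzchar(words)]), method = "radix")
  })
  empties <- names(dict)[lengths(dict) == 0]
  if (length(empties) > 0) {
    warning("empty category kept: ", paste(empties, collapse = ", "),
            call. = FALSE)
  }
  check_disjoint(dict)
  if (!is.null(generic_words)) {
    gen <- intersect(normalize_word(generic_words), unlist(dict))
    if (length(gen) > 0) {
      warning("dictionary contains flagged generic word(s): ",
              paste(gen, collapse = ", "), call. = FALSE)
    }
  }
  structure(dict, class = "keyword_dictionary")
}

check_disjoint <- function(dict) {
  all_words <- unlist(dict, use.names = FALSE)
  dup <- unique(all_words[duplicated(all_words)])
  if (length(dup) > 0) {
    w <- dup[1]
    cats <- names(dict)[vapply(dict, function(k) w %in% k, logical(1))]
    stop(sprintf(
      "word \"%s\" appears in more than one category: %s",
      w, paste(cats, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a keyword dictionary from a JSON or YAML config file
#'
#' The file maps category names to word lists, e.g.
#' `{"solidarity": ["doador", "doadores"], ...}`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param generic_words Optional generic-word list (see
#'   [keyword_dictionary()]).
#' @return A validated `keyword_dictionary`.
#' @export
load_dictionary <- function(path, generic_words = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  raw <- lapply(raw, function(v) as.character(unlist(v)))
  keyword_dictionary(raw, generic_words = generic_words)
}

#' Save a keyword dictionary
#'
#' Inverse of [load_dictionary()] on normalized dictionaries.
#'
#' @param dict A `keyword_dictionary`.
#' @param path Output path; `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "keyword_dictionary"))
  x <- lapply(unclass(dict), as.list)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(unclass(dict), as.character), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Add a keyword to a category
#'
#' The word is normalized first. Adding a word already present in the same
#' category is a no-op; adding one present in another category is an error,
#' since keyword sets must stay disjoint.
#'
#' @param dict A `keyword_dictionary`.
#' @param category An existing category name.
#' @param word A single word form (no spaces).
#' @return The updated dictionary.
#' @export
add_keyword <- function(dict, category, word) {
  stopifnot(inherits(dict, "keyword_dictionary"))
  if (!category %in% names(dict)) {
    stop("unknown category: ", category, call. = FALSE)
  }
  word <- normalize_word(word)
  if (length(word) != 1 || grepl("\\s", word) || !nzchar(word)) {
    stop("keyword must be one single non-empty word", call. = FALSE)
  }
  other <- setdiff(names(dict), category)
  clash <- other[vapply(dict[other], function(k) word %in% k, logical(1))]
  if (length(clash) > 0) {
    stop(sprintf("word \"%s\" already belongs to category %s",
                 word, clash[1]), call. = FALSE)
  }
  dict[[category]] <- sort(unique(c(dict[[category]], word)), method = "radix")
  dict
}

#' Remove a keyword from a category
#'
#' @inheritParams add_keyword
#' @return The updated dictionary; removing an absent word is a no-op.
#' @export
remove_keyword <- function(dict, category, word) {
  stopifnot(inherits(dict, "keyword_dictionary"))
  if (!category %in% names(dict)) {
    stop("unknown category: ", category, call. = FALSE)
  }
  dict[[category]] <- setdiff(dict[[category]], normalize_word(word))
  dict
}

#' Normalize a set of inflected forms of a word
#'
#' The matcher has no morphology: all variations of a word (singular,
#' plural, masculine, feminine) must be listed explicitly. This helper
#' normalizes and deduplicates caller-supplied forms so they can be inserted
#' with [add_keyword()].
#'
#' @param word The base word (included in the output if not already among
#'   `forms`).
#' @param forms Character vector of inflected forms.
#' @return Character vector of unique normalized single-word forms.
#' @examples
#' expand_inflections("doador", c("doador", "doadores", "doadora", "doadoras"))
#' @export
expand_inflections <- function(word, forms = character()) {
  out <- normalize_word(unique(c(as.character(word), as.character(forms))))
  multi <- grepl("\\s", out)
  if (any(multi)) {
    stop("inflected forms must be single words, got: ",
         paste(out[multi], collapse = ", "), call. = FALSE)
  }
  unique(out[nzchar(out)])
}

#' Demonstration keyword dictionary
#'
#' A small illustrative Portuguese dictionary covering the eight default
#' categories, shipped with the package. It demonstrates the dictionary
#' format and feeds the synthetic-corpus generator and the examples; it is
#' not a dictionary tuned on real pages.
#'
#' @return A `keyword_dictionary` with the eight default categories.
#' @export
demo_dictionary <- function() {
  load_dictionary(system.file("extdata", "demo_dictionary.json",
                              package = "postengage", mustWork = TRUE))
}

#' @export
print.keyword_dictionary <- function(x, ...) {
  cat(sprintf("<keyword_dictionary> %d categories, %d keywords\n",
              length(x), sum(lengths(x))))
  for (cat_name in names(x)) {
    words <- x[[cat_name]]
    shown <- paste(utils::head(words, 6), collapse = ", ")
    if (length(words) > 6) shown <- paste0(shown, ", ...")
    cat(sprintf("  %s (%d): %s\n", cat_name, length(words), shown))
  }
  invisible(x)
}
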