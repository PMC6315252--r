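# Text normalization and tokenization shared by the dictionary, classifier
# and word-frequency code. The matching model is deliberately minimal: the
# classifier only "reads" complete words, so normalization must not merge
# forms a dictionary author would consider distinct.

#' Normalize a word form
#'
#' Applies the package-wide word normalization: Unicode NFC composition and
#' lowercase case folding. Diacritics are preserved on purpose: in Portuguese
#' \code{"câncer"} and \code{"cancer"} are different strings, and the matcher
#' compares complete word forms with no further transformation (no stemming,
#' no accent stripping).
#'
#' @param x Character vector of word forms.
#' @return Character vector of normalized forms, same length as `x`.
#' @examples
#' normalize_word(c("Dia", "CÂNCER"))
#' @export
normalize_word <- function(x) {
  stringi::stri_trans_nfc(stringi::stri_trans_tolower(as.character(x)))
}

#' Tokenize post text into normalized word tokens
#'
#' Splits text into maximal runs of Unicode letters, after removing URLs.
#' Digits, punctuation and symbols never enter tokens, and internal hyphens
#' split words (\code{"pré-natal"} becomes \code{"pré"}, \code{"natal"}).
#' Tokens are normalized with [normalize_word()], so they compare directly
#' against dictionary keywords.
#'
#' @param text Character vector of post texts (may be empty or `NA`).
#' @return A list with one character vector of tokens per input element;
#'   empty or `NA` text yields `character(0)`.
#' @examples
#' tokenize("Vamos falar sobre câncer.")
#' tokenize("Leia mais: http://goo.gl/FgJNvv")
#' @export
tokenize <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  # strip URLs before extracting letter runs, else "goo.gl/FgJNvv" leaks
  # tokens like "goo" and "fgjnvv"
  text <- stringi::stri_replace_all_regex(text, "(https?://|www\\.)\\S+", " ")
  toks <- stringi::stri_extract_all_regex(text, "\\p{L}+", omit_no_match = TRUE)
  lapply(toks, normalize_word)
}

#' Round half away from zero
#'
#' The display convention used in report tables (percentages, 1-decimal
#' engagement columns): computation stays at full precision, display rounds
#' half-up. A tiny absolute epsilon absorbs binary representation error in
#' exact .5 boundaries arising from 1-decimal inputs.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals (default 1).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(31.35)  # 31.4, where round() would give 31.3
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}
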