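# Shared text normalization: one normal form for deduplication, the
# duplicate/homonym guard, and corpus matching, so the three can never drift.

# Punctuation class: Unicode punctuation plus the symbol separators that
# terminology strings use as delimiters (* / @ + = < >). Digits and letters
# are never punctuation.
.punct_class <- "[\\p{P}*/@+=<>]"

#' Normalize a term to its lookup key
#'
#' Lowercases, replaces every punctuation character with a space, collapses
#' whitespace runs, and trims. Punctuation is replaced by a space rather than
#' deleted so that `"10*9/L"` yields the three tokens `10 9 l`, which is the
#' behaviour the token-level suppression logic requires. The same key is used
#' for within-concept deduplication, the duplicate/homonym guard, and the
#' corpus recognizer.
#'
#' @param text Character vector of raw term strings.
#' @return Character vector of normalized keys; may contain empty strings
#'   (e.g. for terms made of punctuation only).
#' @examples
#' normalize_key("10*9/L")              # "10 9 l"
#' normalize_key("Alzheimer's disease") # "alzheimer s disease"
#' @export
normalize_key <- function(text) {
  out <- stringr::str_replace_all(text, stringr::regex(.punct_class), " ")
  out <- tolower(out)
  stringr::str_squish(out)
}

#' Tokenize a string with source offsets
#'
#' Tokens are the whitespace-separated units of [normalize_key()]; because
#' punctuation is replaced character-for-character by a space, every token maps
#' back to a character span of the original text.
#'
#' @param text A single character string.
#' @return A tibble with columns `token` (lowercased), `start`, `end`
#'   (1-based, inclusive character offsets into `text`).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  masked <- stringr::str_replace_all(text, stringr::regex(.punct_class), " ")
  loc <- stringr::str_locate_all(masked, "\\S+")[[1]]
  if (nrow(loc) == 0L) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  tibble::tibble(
    token = tolower(stringr::str_sub(masked, loc[, 1L], loc[, 2L])),
    start = as.integer(loc[, 1L]),
    end = as.integer(loc[, 2L])
  )
}

# token vector only, no offsets
term_tokens <- function(text) {
  key <- normalize_key(text)
  if (is.na(key) || !nzchar(key)) return(character())
  strsplit(key, " ", fixed = TRUE)[[1L]]
}

#' Remove stop words from a token sequence
#'
#' @param tokens Either a character vector of lowercase tokens or a tibble as
#'   returned by [tokenize()].
#' @param stoplist Character vector of lowercase stop words.
#' @return Object of the same shape as `tokens`, with stop words removed and
#'   order preserved.
#' @export
remove_stopwords <- function(tokens, stoplist) {
  if (is.data.frame(tokens)) {
    tokens[!tokens$token %in% stoplist, , drop = FALSE]
  } else {
    tokens[!tokens %in% stoplist]
  }
}

#' Test whether a token is a well-formed roman numeral
#'
#' Subtractive notation, range 1-3999. Tokens are expected lowercase (the
#' shared tokenizer lowercases).
#'
#' @param token Character vector.
#' @return Logical vector.
#' @export
is_roman_numeral <- function(token) {
  nzchar(token) &
    grepl("^m{0,3}(cm|cd|d?c{0,3})(xc|xl|l?x{0,3})(ix|iv|v?i{0,3})$", token)
}

#' Test whether a token is an arabic number
#'
#' True for strings of digits, optionally with one decimal point flanked by
#' digits. Note that under the shared tokenizer a decimal point is punctuation,
#' so `"0.5"` arrives as two tokens; the predicate itself still accepts the
#' string `"0.5"`.
#'
#' @param token Character vector.
#' @return Logical vector.
#' @export
is_arabic_number <- function(token) {
  grepl("^[0-9]+(\\.[0-9]+)?$", token)
}

#' Count the words of a raw term
#'
#' Splits the raw text on whitespace without touching punctuation, so
#' `"insulin-like"` is a single word.
#'
#' @param text Character vector.
#' @return Integer vector of word counts.
#' @export
word_count <- function(text) {
  text <- trimws(text)
  out <- stringr::str_count(text, "\\S+")
  out[!nzchar(text) | is.na(text)] <- 0L
  as.integer(out)
}
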