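# The eight suppression predicates. Each is a pure function of the term text
# (plus resource lists / the Chemicals & Drugs flag) and returns a verdict:
# list(suppressed = flag, trigger = matched pattern text).

verdict <- function(suppressed, trigger = "") {
  list(suppressed = suppressed, trigger = if (suppressed) trigger else "")
}

#' Suppression rule S1: short tokens
#'
#' Tokenizes the term and removes stop words; the term is suppressed when
#' nothing remains, or when every remaining token is a single character, an
#' arabic number, or a roman numeral. Applied token by token, so `"10*9/L"`
#' (tokens `10 9 l`) is suppressed, and a concept whose only term is a stop
#' word (e.g. `"WHILE"`) is suppressed outright.
#'
#' @param term Term string.
#' @param stoplist Lowercase stop-word list.
#' @return A verdict: `list(suppressed, trigger)`.
#' @export
sp_short_token <- function(term, stoplist = pubmed_stopwords()) {
  toks <- remove_stopwords(term_tokens(term), stoplist)
  if (length(toks) == 0L) return(verdict(TRUE, normalize_key(term)))
  short <- nchar(toks) == 1L | is_arabic_number(toks) | is_roman_numeral(toks)
  verdict(all(short), paste(toks, collapse = " "))
}

#' Suppression rule S2: dosages
#'
#' Suppresses terms containing a dosage: a number immediately followed
#' (optionally after one space) by a percent, gram, microgram or milliliter
#' unit token (e.g. `"Oxygen 2%"`). The unit list deliberately excludes "mg";
#' see [dosage_units()] to extend it.
#'
#' @param term Term string.
#' @param units Unit tokens to recognize.
#' @return A verdict.
#' @export
sp_dosages <- function(term, units = dosage_units()) {
  units <- units[order(-nchar(units))]
  alt <- paste(vapply(units, escape_regex, character(1L)), collapse = "|")
  pat <- stringr::regex(
    sprintf("(?<![[:alnum:]])[0-9]+(?:\\.[0-9]+)? ?(?:%s)(?![[:alpha:]])", alt),
    ignore_case = TRUE
  )
  hit <- stringr::str_extract(term, pat)
  verdict(!is.na(hit), if (is.na(hit)) "" else hit)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Suppression rule S3: at-sign
#'
#' Suppresses any term containing the `@` character.
#'
#' @param term Term string.
#' @return A verdict.
#' @export
sp_at_sign <- function(term) {
  verdict(grepl("@", term, fixed = TRUE), "@")
}

#' Suppression rule S4: enzyme classification numbers
#'
#' Suppresses terms containing an IUPAC enzyme classification number: the
#' literal `EC` (case-sensitive, at a word boundary) followed by an optional
#' space and 2-4 dot-separated fields of digits or `-` (e.g. `"EC 2.7.1.112"`,
#' `"EC 2.7.1.-"`). EC numbers usually denote an enzyme class, not the
#' specific enzyme the concept stands for.
#'
#' @param term Term string.
#' @return A verdict.
#' @export
sp_ec_number <- function(term) {
  pat <- "(?<![[:alnum:]])EC ?(?:[0-9]+|-)(?:\\.(?:[0-9]+|-)){1,3}"
  hit <- stringr::str_extract(term, stringr::regex(pat))
  verdict(!is.na(hit), if (is.na(hit)) "" else hit)
}

# shared by S5/S6: qualifier code at the end of a term, either preceded by a
# comma ("Injury, NEC") or within parentheses/brackets preceded by a space
# ("Injury (NEC)"). Code matching is case-sensitive: NEC/NOS are coding
# conventions, always upper case.
terminal_code <- function(term, code) {
  pats <- c(
    sprintf(",\\s*%s\\s*$", code),
    sprintf("\\s\\(%s\\)\\s*$", code),
    sprintf("\\s\\[%s\\]\\s*$", code)
  )
  for (p in pats) {
    hit <- stringr::str_extract(term, p)
    if (!is.na(hit)) return(trimws(hit))
  }
  NA_character_
}

substring_hit <- function(term, needles) {
  lower <- tolower(term)
  for (n in needles) {
    if (grepl(n, lower, fixed = TRUE)) return(n)
  }
  NA_character_
}

#' Suppression rule S5: classification qualifiers
#'
#' Suppresses terms carrying a "not elsewhere classified" qualifier: the
#' case-insensitive substrings `"not elsewhere classified"`, `"unclassified"`
#' or `"without mention"` anywhere, or `NEC` at the end of the term preceded
#' by a comma, or `(NEC)`/`[NEC]` at the end preceded by a space.
#'
#' @param term Term string.
#' @return A verdict.
#' @export
sp_any_classification <- function(term) {
  hit <- substring_hit(term, c("not elsewhere classified", "unclassified",
                               "without mention"))
  if (is.na(hit)) hit <- terminal_code(term, "NEC")
  verdict(!is.na(hit), if (is.na(hit)) "" else hit)
}

#' Suppression rule S6: underspecification qualifiers
#'
#' Suppresses terms carrying a "not otherwise specified" qualifier: the
#' case-insensitive substrings `"not otherwise specified"`, `"not specified"`
#' or `"unspecified"` anywhere, or `NOS` at the end of the term preceded by a
#' comma, or `(NOS)`/`[NOS]` at the end preceded by a space.
#'
#' @param term Term string.
#' @return A verdict.
#' @export
sp_any_underspecification <- function(term) {
  hit <- substring_hit(term, c("not otherwise specified", "not specified",
                               "unspecified"))
  if (is.na(hit)) hit <- terminal_code(term, "NOS")
  verdict(!is.na(hit), if (is.na(hit)) "" else hit)
}

#' Suppression rule S7: miscellaneous vague keywords
#'
#' Suppresses terms that (case-insensitively) start with `"other "`,
#' `"deprecated "`, `"unknown "`, `"obsolete "`, `"miscellaneous "` or
#' `"no "`, end with `" other"`, or consist solely of one of the keywords
#' (`"Other"`, `"Deprecated"`, `"Unknown"`, `"Obsolete"`, `"Miscellaneous"`).
#' The bare word `"no"` is not suppressed here; a term reduced to it falls to
#' the short-token rule.
#'
#' @param term Term string.
#' @return A verdict.
#' @export
sp_miscellaneous <- function(term) {
  lower <- tolower(trimws(term))
  begin <- c("other", "deprecated", "unknown", "obsolete", "miscellaneous", "no")
  for (kw in begin) {
    if (startsWith(lower, paste0(kw, " "))) return(verdict(TRUE, kw))
  }
  if (endsWith(lower, " other")) return(verdict(TRUE, "other"))
  whole <- c("other", "deprecated", "unknown", "obsolete", "miscellaneous")
  if (lower %in% whole) return(verdict(TRUE, lower))
  verdict(FALSE)
}

#' Suppression rule S8: terms longer than five words
#'
#' Suppresses terms of more than five raw whitespace-separated words (e.g.
#' `"Head and Neck Squamous Cell Carcinoma"`); hyphenated compounds count as
#' one word. Not applied to concepts in the semantic group Chemicals & Drugs,
#' whose systematic names are legitimately long.
#'
#' @param term Term string.
#' @param in_chem_group Is the term's concept in Chemicals & Drugs?
#' @return A verdict.
#' @export
sp_words_gt5 <- function(term, in_chem_group = FALSE) {
  n <- word_count(term)
  verdict(!isTRUE(in_chem_group) && n > 5L, sprintf("%d words", n))
}
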