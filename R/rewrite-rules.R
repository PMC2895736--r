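# The nine rewrite rules. Each consumes one term (plus semantic context) and
# returns zero or more candidate synonym strings, before guard checking. No
# rule ever emits its own input or an empty string.

# drop empty / unchanged candidates
emit <- function(term, out) {
  out <- trimws(out)
  unique(out[nzchar(out) & out != term])
}

#' Rewrite rule 1: syntactic inversion
#'
#' A term of the form `"A, B"` containing exactly one comma-space pattern and
#' no preposition or conjunction is inverted to `"B A"` (e.g. `"Failure,
#' Renal"` to `"Renal Failure"`). Tokens are compared case-insensitively
#' against the blocking list after stripping trailing punctuation.
#'
#' @param term Term string.
#' @param prepositions Blocking word list (lowercase).
#' @return Character vector of candidates (length 0 or 1).
#' @export
rw_syntactic_inversion <- function(term, prepositions = rule_prepositions()) {
  if (stringr::str_count(term, stringr::fixed(", ")) != 1L) return(character())
  raw_tokens <- strsplit(trimws(term), "\\s+")[[1L]]
  raw_tokens <- tolower(sub("[[:punct:]]+$", "", raw_tokens))
  if (any(raw_tokens %in% prepositions)) return(character())
  parts <- stringr::str_split_fixed(term, stringr::fixed(", "), 2L)
  emit(term, paste(trimws(parts[1L, 2L]), trimws(parts[1L, 1L])))
}

#' Rewrite rule 2: possessives
#'
#' Removes every possessive `'s` at a word end (before whitespace or at the
#' end of the term); both the ASCII apostrophe and U+2019 are recognized.
#' Plural possessives (`s'`) are left alone.
#'
#' @param term Term string.
#' @return Character vector of candidates (length 0 or 1).
#' @export
rw_possessives <- function(term) {
  out <- stringr::str_replace_all(term, "['’]s(?=\\s|$)", "")
  emit(term, out)
}

# Schwartz-Hearst right-to-left character matching: find the best long form
# for `sf` inside `lf`, or NULL. The last characters match first; the first
# character of the short form must match at the start of a word in the long
# form; the long form is then extended left to that word's boundary.
find_best_long_form <- function(sf, lf) {
  s_chars <- strsplit(tolower(sf), "")[[1L]]
  l_chars <- strsplit(tolower(lf), "")[[1L]]
  si <- length(s_chars)
  li <- length(l_chars)
  alnum <- function(ch) grepl("[[:alnum:]]", ch)
  while (si >= 1L) {
    ch <- s_chars[si]
    if (!alnum(ch)) {
      si <- si - 1L
      next
    }
    repeat {
      if (li < 1L) return(NULL)
      ok <- l_chars[li] == ch
      if (ok && si == 1L && li > 1L && alnum(l_chars[li - 1L])) ok <- FALSE
      if (ok) break
      li <- li - 1L
    }
    si <- si - 1L
    li <- li - 1L
  }
  start <- li + 1L
  prefix <- substr(lf, 1L, start - 1L)
  ws <- gregexpr("\\s", prefix)[[1L]]
  word_start <- if (ws[1L] == -1L) 1L else max(ws) + 1L
  trimws(substr(lf, word_start, nchar(lf)))
}

#' Rewrite rule 3: short form / long form
#'
#' Treats a term ending in a parenthesized expression as an abbreviation
#' definition and pairs the short form with its long form by the
#' Schwartz-Hearst algorithm (right-to-left character matching; candidate
#' short forms are 2-10 characters, at most two words, contain a letter and
#' start with an alphanumeric; the long-form search window is
#' `min(|SF|+5, |SF|*2)` words left of the parenthesis). Two extra conditions
#' adapt the algorithm from running text to dictionary entries: the short form
#' must sit at the very end of the term, and the first letters of short and
#' long form must agree (case-insensitively). On success both forms are
#' emitted.
#'
#' @param term Term string.
#' @return Character vector of candidates (length 0 or 2).
#' @export
rw_short_long_form <- function(term) {
  m <- stringr::str_match(term, "^(.*\\S)\\s*\\(([^()]+)\\)\\s*$")
  if (is.na(m[1L, 1L])) return(character())
  before <- m[1L, 2L]
  sf <- trimws(m[1L, 3L])
  n_sf <- nchar(sf)
  if (n_sf < 2L || n_sf > 10L) return(character())
  if (stringr::str_count(sf, "\\S+") > 2L) return(character())
  if (!grepl("[[:alpha:]]", sf)) return(character())
  if (!grepl("^[[:alnum:]]", sf)) return(character())
  words <- strsplit(trimws(before), "\\s+")[[1L]]
  window <- min(n_sf + 5L, n_sf * 2L)
  candidate <- paste(utils::tail(words, window), collapse = " ")
  lf <- find_best_long_form(sf, candidate)
  if (is.null(lf) || !nzchar(lf)) return(character())
  if (nchar(lf) < nchar(sf)) return(character())
  if (grepl(paste0(sf, " "), lf, fixed = TRUE) || endsWith(lf, sf)) {
    return(character())
  }
  if (tolower(substr(lf, 1L, 1L)) != tolower(substr(sf, 1L, 1L))) {
    return(character())
  }
  emit(term, c(lf, sf))
}

#' Rewrite rule 4: angular brackets
#'
#' Removes every non-nested `<...>` span anywhere in the term (these spans
#' carry meta-information such as homonymy markers), collapses whitespace and
#' trims.
#'
#' @param term Term string.
#' @return Character vector of candidates (length 0 or 1).
#' @export
rw_angular_brackets <- function(term) {
  if (!stringr::str_detect(term, "<[^<>]*>")) return(character())
  out <- stringr::str_squish(stringr::str_replace_all(term, "<[^<>]*>", " "))
  emit(term, out)
}

#' Rewrite rule 5: semantic type
#'
#' If the term ends with a parenthesized expression that case-insensitively
#' equals a Semantic Network type name (e.g. `"Surgical intervention
#' (finding)"`), the parenthetical is removed. Only parentheses are matched,
#' not brackets.
#'
#' @param term Term string.
#' @param type_names Semantic-type name list.
#' @return Character vector of candidates (length 0 or 1).
#' @export
rw_semantic_type <- function(term, type_names = semantic_type_names()) {
  m <- stringr::str_match(term, "^(.*)\\(([^()]*)\\)\\s*$")
  if (is.na(m[1L, 1L])) return(character())
  inner <- trimws(m[1L, 3L])
  if (!tolower(inner) %in% tolower(type_names)) return(character())
  emit(term, trimws(m[1L, 2L], which = "right"))
}

# balanced-depth scans (not regex) so that "t(3;6)(p13;q25)" strips exactly
# its final group; unbalanced delimiters yield no candidate
strip_leading_group <- function(term, open, close) {
  chars <- strsplit(term, "")[[1L]]
  if (length(chars) == 0L || chars[1L] != open) return(NULL)
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == open) depth <- depth + 1L
    else if (chars[i] == close) depth <- depth - 1L
    if (depth == 0L) {
      return(trimws(substr(term, i + 1L, nchar(term)), which = "left"))
    }
  }
  NULL
}

strip_trailing_group <- function(term, open, close) {
  chars <- strsplit(term, "")[[1L]]
  n <- length(chars)
  if (n == 0L || chars[n] != close) return(NULL)
  depth <- 0L
  for (i in rev(seq_len(n))) {
    if (chars[i] == close) depth <- depth + 1L
    else if (chars[i] == open) depth <- depth - 1L
    if (depth == 0L) {
      return(trimws(substr(term, 1L, i - 1L), which = "right"))
    }
  }
  NULL
}

rw_group_rule <- function(term, in_chem_group, strip, open, close) {
  if (isTRUE(in_chem_group)) return(character())
  out <- strip(term, open, close)
  if (is.null(out)) return(character())
  emit(term, out)
}

#' Rewrite rules 6-9: parentheticals at term boundaries
#'
#' Remove a balanced parenthesized or bracketed group at the beginning or end
#' of a term (e.g. `"(protein) methionine-R-sulfoxide reductase"`,
#' `"[D]Respiratory abnormalities"`, `"flagellar filament (sensu Bacteria)"`,
#' `"Abstracts [Publication Type]"`). None of the four rules applies to terms
#' of concepts in the semantic group Chemicals & Drugs, whose names routinely
#' begin or end with such groups. An unbalanced delimiter yields no candidate.
#'
#' @param term Term string.
#' @param in_chem_group Is the term's concept in Chemicals & Drugs?
#' @return Character vector of candidates (length 0 or 1).
#' @export
rw_begin_parentheses <- function(term, in_chem_group = FALSE) {
  rw_group_rule(term, in_chem_group, strip_leading_group, "(", ")")
}

#' @rdname rw_begin_parentheses
#' @export
rw_begin_brackets <- function(term, in_chem_group = FALSE) {
  rw_group_rule(term, in_chem_group, strip_leading_group, "[", "]")
}

#' @rdname rw_begin_parentheses
#' @export
rw_end_parentheses <- function(term, in_chem_group = FALSE) {
  rw_group_rule(term, in_chem_group, strip_trailing_group, "(", ")")
}

#' @rdname rw_begin_parentheses
#' @export
rw_end_brackets <- function(term, in_chem_group = FALSE) {
  rw_group_rule(term, in_chem_group, strip_trailing_group, "[", "]")
}
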