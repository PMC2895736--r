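# Loaders for the bundled word lists. Every list is config-replaceable: each
# loader accepts a path to a plain-text file, one entry per line, "#" comments
# and blank lines ignored.

read_wordlist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

pkg_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "umlstidy", mustWork = TRUE)
  path
}

#' Bundled PubMed stop-word list
#'
#' The 133-word historical PubMed stop-word list, lowercased, used by the
#' short-token suppression rule. The exact stop-word list in use by PubMed has
#' changed over the years; the bundled snapshot is the widely circulated
#' 133-word version and can be replaced via `path`.
#'
#' @param path Optional path to an alternative stop-word file.
#' @return Character vector of lowercase stop words.
#' @export
pubmed_stopwords <- function(path = NULL) {
  tolower(read_wordlist(path %||% pkg_extdata("pubmed_stopwords.txt")))
}

#' Bundled UMLS Semantic Network type names
#'
#' The semantic-type names of the 2007-era Semantic Network, used by the
#' semantic-type rewrite rule to recognize parentheticals such as
#' `"(finding)"`. Matching is case-insensitive.
#'
#' @param path Optional path to an alternative type-name file.
#' @return Character vector of type names.
#' @export
semantic_type_names <- function(path = NULL) {
  read_wordlist(path %||% pkg_extdata("semantic_types.txt"))
}

#' Preposition/conjunction list for syntactic inversion
#'
#' Minimal closed-class English set; a term containing any of these words is
#' not inverted.
#'
#' @param path Optional path to an alternative list.
#' @return Character vector of lowercase words.
#' @export
rule_prepositions <- function(path = NULL) {
  tolower(read_wordlist(path %||% pkg_extdata("prepositions.txt")))
}

#' Dosage unit tokens
#'
#' Unit tokens recognized by the dosage suppression rule: percent, gram,
#' microgram and milliliter families. Deliberately excludes "mg"; extend via
#' `extra` if a broader net is wanted.
#'
#' @param extra Additional unit tokens to recognize.
#' @return Character vector of unit tokens.
#' @export
dosage_units <- function(extra = character()) {
  c(
    "%", "percent",
    "g", "gm", "gram", "grams",
    "mcg", "ug", "µg", "microgram", "micrograms",
    "ml", "milliliter", "milliliters",
    extra
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
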