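# Shared helpers for the test suite.

# Dispatch a rewrite rule by id on a single term.
run_rewrite <- function(rule_id, term, in_chem_group = FALSE) {
  switch(rule_id,
    "1" = rw_syntactic_inversion(term),
    "2" = rw_possessives(term),
    "3" = rw_short_long_form(term),
    "4" = rw_angular_brackets(term),
    "5" = rw_semantic_type(term),
    "6" = rw_begin_parentheses(term, in_chem_group),
    "7" = rw_begin_brackets(term, in_chem_group),
    "8" = rw_end_parentheses(term, in_chem_group),
    "9" = rw_end_brackets(term, in_chem_group),
    stop("unknown rewrite rule ", rule_id)
  )
}

# Dispatch a suppression rule by id; returns TRUE if the term is suppressed.
run_suppression <- function(rule_id, term, in_chem_group = FALSE) {
  v <- switch(rule_id,
    "S1" = sp_short_token(term),
    "S2" = sp_dosages(term),
    "S3" = sp_at_sign(term),
    "S4" = sp_ec_number(term),
    "S5" = sp_any_classification(term),
    "S6" = sp_any_underspecification(term),
    "S7" = sp_miscellaneous(term),
    "S8" = sp_words_gt5(term, in_chem_group),
    stop("unknown suppression rule ", rule_id)
  )
  v$suppressed
}

# Brute-force recognizer oracle: for every indexed record, slide its token
# sequence over the document tokens and count every hit. Quadratic and
# obviously correct; annotate() must agree exactly.
brute_force_matches <- function(document, index) {
  toks <- tokenize(document)$token
  n <- length(toks)
  recs <- index$records
  rows <- vector("list", 0L)
  for (r in seq_len(nrow(recs))) {
    kt <- strsplit(recs$key[r], " ", fixed = TRUE)[[1]]
    L <- length(kt)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (all(toks[s:(s + L - 1L)] == kt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          token_start = s, token_end = s + L,
          concept_id = recs$concept_id[r], string_id = recs$string_id[r],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(token_start = integer(), token_end = integer(),
                      concept_id = character(), string_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$token_start, out$token_end, out$concept_id, out$string_id), ,
      drop = FALSE]
}

# Canonical comparable form of a match table (shared columns, no row names).
match_signature <- function(m) {
  m <- as.data.frame(m)[, c("token_start", "token_end", "concept_id",
                            "string_id")]
  m <- m[order(m$token_start, m$token_end, m$concept_id, m$string_id), ,
         drop = FALSE]
  rownames(m) <- NULL
  m
}

# Load the bundled worked-example lexicon plus its semantic typing.
golden_setup <- function() {
  g <- golden_fixture()
  lex <- as_lexicon(read_concept_table(g$concept_table, dialect = "reduced"))
  sm <- read_semantic_types(g$semantic_types, g$semantic_groups)
  list(golden = g, lexicon = lex, semmap = sm)
}
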