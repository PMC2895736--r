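# Minimal general-purpose concept recognizer: case-insensitive,
# punctuation-ignoring dictionary lookup with largest match OFF (nested terms
# count both for the longer and the shorter term), plus corpus statistics.

#' Build a term index for corpus matching
#'
#' Indexes the normalized token sequences of all lexicon records. Matching is
#' token-sequence exact, never character-substring: "nose" can never match
#' inside "diagnosed". Records whose text normalizes to an empty key are
#' skipped and reported via the `"skipped"` attribute.
#'
#' @param lexicon A `lexicon`.
#' @return A `term_index`.
#' @export
build_index <- function(lexicon) {
  recs <- lexicon_records(lexicon)
  if (is.null(recs$norm_key)) recs$norm_key <- normalize_key(recs$text)
  keyed <- nzchar(recs$norm_key)
  skipped <- recs[!keyed, , drop = FALSE]
  recs <- recs[keyed, , drop = FALSE]
  entries <- tibble::tibble(
    key = recs$norm_key,
    n_tokens = stringr::str_count(recs$norm_key, stringr::fixed(" ")) + 1L,
    concept_id = recs$concept_id,
    string_id = recs$string_id,
    provenance = recs$provenance,
    rule_id = recs$rule_id
  )
  env <- new.env(parent = emptyenv(), size = max(29L, nrow(entries)))
  if (nrow(entries) > 0L) {
    list2env(split(seq_len(nrow(entries)), entries$key), envir = env)
  }
  structure(
    list(env = env, records = entries,
         lengths = sort(unique(entries$n_tokens))),
    class = "term_index", skipped = skipped
  )
}

#' @export
print.term_index <- function(x, ...) {
  cat(sprintf("<term_index> %d records, %d distinct keys, key lengths %s\n",
              nrow(x$records), length(unique(x$records$key)),
              paste(x$lengths, collapse = ",")))
  invisible(x)
}

empty_matches <- function() {
  tibble::tibble(
    doc_id = integer(), token_start = integer(), token_end = integer(),
    key = character(), concept_id = character(), string_id = character(),
    provenance = character(), rule_id = character()
  )
}

#' Annotate one document
#'
#' Tokenizes the document with the shared normalization and reports every
#' index key occurring as a contiguous token subsequence — including keys
#' nested inside longer matches and overlapping matches (largest match off).
#' One row is emitted per (occurrence, record) pairing; a key held by several
#' records yields several rows for the same span.
#'
#' @param document A single document string.
#' @param index A `term_index`.
#' @param doc_id Document id to stamp on the matches.
#' @return Tibble of match events ordered by (token_start, token_end):
#'   `doc_id`, `token_start`, `token_end` (half-open token span), `key`,
#'   `concept_id`, `string_id`, `provenance`, `rule_id`.
#' @export
annotate <- function(document, index, doc_id = 1L) {
  stopifnot(inherits(index, "term_index"))
  toks <- tokenize(document)$token
  n <- length(toks)
  hits <- list()
  for (L in index$lengths) {
    if (L > n) break
    starts <- seq_len(n - L + 1L)
    keys <- if (L == 1L) toks else
      vapply(starts, function(i) paste(toks[i:(i + L - 1L)], collapse = " "),
             character(1L))
    for (s in starts) {
      rows <- get0(keys[s], envir = index$env, inherits = FALSE)
      if (is.null(rows)) next
      rec <- index$records[rows, , drop = FALSE]
      hits[[length(hits) + 1L]] <- tibble::tibble(
        doc_id = doc_id, token_start = s, token_end = s + L,
        key = keys[s], concept_id = rec$concept_id,
        string_id = rec$string_id, provenance = rec$provenance,
        rule_id = rec$rule_id
      )
    }
  }
  if (length(hits) == 0L) return(empty_matches())
  out <- do.call(rbind, hits)
  out[order(out$token_start, out$token_end, out$concept_id, out$string_id), ]
}

stats_block <- function(matches) {
  tibble::tibble(
    occurrences = nrow(matches),
    distinct_terms = length(unique(matches$string_id)),
    distinct_concepts = length(unique(matches$concept_id))
  )
}

#' Corpus-level match statistics
#'
#' Aggregates [annotate()] over all documents. Occurrences count every
#' (match, record) pairing once; distinct terms count string ids; distinct
#' concepts count concept ids. Besides the totals, tallies are broken down by
#' record provenance (original vs generated) and per string, so both the
#' per-(string, concept) and the per-string reading of an occurrence are
#' recoverable.
#'
#' @param documents Character vector of documents (one per element).
#' @param index A `term_index`.
#' @return A `corpus_stats` object: list with `total`, `by_provenance`,
#'   `by_string`, and the full `matches` table.
#' @export
corpus_stats <- function(documents, index) {
  per_doc <- lapply(seq_along(documents), function(i) {
    annotate(documents[i], index, doc_id = i)
  })
  matches <- if (length(per_doc)) do.call(rbind, per_doc) else empty_matches()
  prov <- unique(matches$provenance)
  by_prov <- tibble::as_tibble(do.call(rbind, lapply(prov, function(p) {
    cbind(tibble::tibble(provenance = p),
          stats_block(matches[matches$provenance == p, , drop = FALSE]))
  })))
  counts <- table(matches$string_id)
  by_string <- tibble::tibble(
    string_id = names(counts),
    occurrences = as.integer(counts)
  )
  structure(list(
    total = stats_block(matches),
    by_provenance = by_prov,
    by_string = by_string,
    matches = matches
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats>\n")
  print(x$total)
  invisible(x)
}

#' Per-rule corpus impact of a rule application
#'
#' For every rule enabled in `outcome`, measures what its generated terms add
#' to the corpus matches (rewrite impact) and what its suppressed terms used
#' to match (suppression impact): occurrences, distinct terms, distinct
#' concepts attributable to that rule.
#'
#' @param documents Character vector of documents.
#' @param before A `lexicon`, the input that `outcome` was produced from
#'   (unused directly, kept for the call signature's symmetry and validated
#'   against the suppressed records).
#' @param outcome A `rule_outcome` from [apply_rules()]; its event log is
#'   required.
#' @return Tibble with one row per enabled rule: `rule_id`, `kind`
#'   (`"rewrite"` or `"suppression"`), `occurrences`, `distinct_terms`,
#'   `distinct_concepts`.
#' @export
before_after_delta <- function(documents, before, outcome) {
  if (!inherits(outcome, "rule_outcome") || is.null(outcome$events)) {
    stop("'outcome' must be a rule_outcome with an event log", call. = FALSE)
  }
  rule_stats <- function(recs) {
    if (nrow(recs) == 0L) {
      return(tibble::tibble(occurrences = 0L, distinct_terms = 0L,
                            distinct_concepts = 0L))
    }
    corpus_stats(documents, build_index(new_lexicon(recs)))$total
  }
  rows <- lapply(outcome$report$rule_id, function(rid) {
    if (rid %in% rewrite_ids) {
      recs <- outcome$lexicon$records
      recs <- recs[recs$provenance == "generated" & recs$rule_id == rid, ,
                   drop = FALSE]
      kind <- "rewrite"
    } else {
      recs <- outcome$suppressed
      recs <- recs[recs$suppressed_by == rid, , drop = FALSE]
      recs$suppressed_by <- NULL
      kind <- "suppression"
    }
    cbind(tibble::tibble(rule_id = rid, kind = kind), rule_stats(recs))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
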