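# Reading, filtering, deduplicating and writing concept-term tables in the
# UMLS RRF pipe-delimited dialects, plus the semantic-type/group tables.

# Field maps. Rows carry a trailing pipe, so a row with n fields has n "|"
# characters. The reduced 5-field dialect keeps fixtures hand-readable.
.dialects <- list(
  mrconso = list(n_fields = 18L, concept_id = 1L, language = 2L, string_id = 6L,
                 source_vocab = 12L, term_type = 13L, text = 15L, suppress = 17L),
  reduced = list(n_fields = 5L, concept_id = 1L, language = 2L, string_id = 3L,
                 suppress = 4L, text = 5L)
)

#' Read a concept-term table
#'
#' Parses a pipe-delimited concept-term table in either the full 18-field
#' MRCONSO dialect or a reduced 5-field dialect
#' (`concept_id|language|string_id|suppress|text|`). The dialect is declared,
#' never sniffed. Raw rows are preserved byte-for-byte so that untouched rows
#' round-trip identically through [write_concept_table()].
#'
#' @param path Path to the table (UTF-8).
#' @param dialect `"mrconso"` or `"reduced"`.
#' @return A tibble of term records, one per row, in input order, with columns
#'   `concept_id`, `string_id`, `text`, `language`, `source_vocab`,
#'   `term_type`, `suppressible`, `provenance`, `rule_id`, `raw`.
#' @export
read_concept_table <- function(path, dialect = c("mrconso", "reduced")) {
  dialect <- match.arg(dialect)
  d <- .dialects[[dialect]]
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) return(empty_records())
  n_sep <- stringr::str_count(lines, stringr::fixed("|"))
  bad <- which(n_sep != d$n_fields)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed row at line %d of '%s': expected %d pipe-delimited fields, found %d",
      bad[1L], path, d$n_fields, n_sep[bad[1L]]
    ), call. = FALSE)
  }
  fields <- stringr::str_split_fixed(lines, stringr::fixed("|"), d$n_fields + 1L)
  col <- function(name) {
    if (is.null(d[[name]])) rep(NA_character_, length(lines)) else fields[, d[[name]]]
  }
  tibble::tibble(
    concept_id = col("concept_id"),
    string_id = col("string_id"),
    text = col("text"),
    language = col("language"),
    source_vocab = col("source_vocab"),
    term_type = col("term_type"),
    suppressible = col("suppress"),
    provenance = "original",
    rule_id = NA_character_,
    raw = lines
  )
}

empty_records <- function() {
  tibble::tibble(
    concept_id = character(), string_id = character(), text = character(),
    language = character(), source_vocab = character(), term_type = character(),
    suppressible = character(), provenance = character(), rule_id = character(),
    raw = character()
  )
}

#' Default record filtering
#'
#' Drops records marked suppressible by the NLM (any `SUPPRESS` flag other
#' than `"N"` or empty), records in a language other than English (`"ENG"`),
#' and records whose text is longer than 255 characters.
#'
#' @param records A term-record tibble from [read_concept_table()].
#' @return The filtered tibble, input order preserved.
#' @export
filter_default <- function(records) {
  keep <- records$suppressible %in% c("N", "") &
    records$language == "ENG" &
    nchar(records$text) <= 255L
  records[keep, , drop = FALSE]
}

#' Deduplicate records within each concept
#'
#' Two strings are duplicates within a concept when they share the same
#' normalized key (lowercased, punctuation removed; see [normalize_key()]).
#' The first record in input order is kept. Identical strings under different
#' concepts are homonyms, not duplicates, and are all kept.
#'
#' @param records A term-record tibble.
#' @return A `lexicon` object holding the surviving records and a
#'   normalized-key index.
#' @export
deduplicate_within_concept <- function(records) {
  records$norm_key <- normalize_key(records$text)
  dup <- duplicated(paste(records$concept_id, records$norm_key, sep = "\r"))
  new_lexicon(records[!dup, , drop = FALSE])
}

# Lexicon: record tibble + environment index from normalized key to the
# concept ids holding that key. The index is what the duplicate/homonym guard
# consults; it is rebuilt whenever the record set is replaced wholesale.
new_lexicon <- function(records) {
  if (is.null(records$norm_key)) records$norm_key <- normalize_key(records$text)
  keyed <- nzchar(records$norm_key)
  index <- new.env(parent = emptyenv(), size = max(29L, sum(keyed)))
  if (any(keyed)) {
    by_key <- split(records$concept_id[keyed], records$norm_key[keyed])
    list2env(by_key, envir = index)
  }
  structure(list(records = records, index = index), class = "lexicon")
}

#' Coerce to a lexicon
#'
#' A record tibble is passed through [filter_default()] and
#' [deduplicate_within_concept()] (both idempotent); a `lexicon` is returned
#' unchanged.
#'
#' @param x A `lexicon` or a term-record tibble.
#' @return A `lexicon`.
#' @export
as_lexicon <- function(x) {
  if (inherits(x, "lexicon")) return(x)
  deduplicate_within_concept(filter_default(x))
}

#' Records held by a lexicon
#' @param x A `lexicon`.
#' @return The record tibble.
#' @export
lexicon_records <- function(x) {
  stopifnot(inherits(x, "lexicon"))
  x$records
}

# concept ids holding a normalized key ("" never indexed)
index_concepts <- function(lexicon, key) {
  if (!nzchar(key)) return(character())
  get0(key, envir = lexicon$index, inherits = FALSE, ifnotfound = character())
}

#' @export
print.lexicon <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<lexicon> %d terms, %d concepts (%d generated)\n",
    nrow(r), length(unique(r$concept_id)), sum(r$provenance == "generated")
  ))
  invisible(x)
}

#' Read concept semantic types and their group mapping
#'
#' @param concept_type_path MRSTY-dialect file
#'   (`concept_id|type_id|tree_number|type_name|...`, trailing pipe).
#' @param group_map_path Semantic-group mapping
#'   (`group_abbrev|group_name|type_id|type_name`, no trailing pipe).
#' @return A `semtype_map` object supporting [semantic_groups()] and
#'   [in_semantic_group()]. A concept belongs to a group if any of its types
#'   maps to it; types absent from the group map resolve to `"ungrouped"`.
#' @export
read_semantic_types <- function(concept_type_path, group_map_path) {
  sty <- readLines(concept_type_path, encoding = "UTF-8", warn = FALSE)
  sty <- sty[nzchar(sty)]
  n_sep <- stringr::str_count(sty, stringr::fixed("|"))
  bad <- which(n_sep < 4L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of '%s': expected at least 4 fields",
                 bad[1L], concept_type_path), call. = FALSE)
  }
  f <- stringr::str_split_fixed(sty, stringr::fixed("|"), 5L)
  concept_types <- if (length(sty)) split(f[, 4L], f[, 1L]) else list()

  grp <- readLines(group_map_path, encoding = "UTF-8", warn = FALSE)
  grp <- grp[nzchar(grp)]
  n_sep <- stringr::str_count(grp, stringr::fixed("|"))
  bad <- which(n_sep < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of '%s': expected 4 fields",
                 bad[1L], group_map_path), call. = FALSE)
  }
  g <- stringr::str_split_fixed(grp, stringr::fixed("|"), 5L)
  type_group <- stats::setNames(g[, 2L], tolower(g[, 4L]))
  if (anyDuplicated(names(type_group))) {
    dup <- names(type_group)[duplicated(names(type_group))][1L]
    if (length(unique(type_group[names(type_group) == dup])) > 1L) {
      stop(sprintf("semantic type '%s' maps to more than one group", dup),
           call. = FALSE)
    }
    type_group <- type_group[!duplicated(names(type_group))]
  }
  structure(list(concept_types = concept_types, type_group = type_group),
            class = "semtype_map")
}

#' Semantic groups of a concept
#' @param map A `semtype_map`.
#' @param concept_id Concept identifier.
#' @return Character vector of group names (possibly including `"ungrouped"`);
#'   empty for an untyped concept.
#' @export
semantic_groups <- function(map, concept_id) {
  stopifnot(inherits(map, "semtype_map"))
  types <- map$concept_types[[concept_id]]
  if (is.null(types)) return(character())
  groups <- map$type_group[tolower(types)]
  groups[is.na(groups)] <- "ungrouped"
  unique(unname(groups))
}

#' Does a concept belong to a semantic group?
#' @inheritParams semantic_groups
#' @param group Group name, e.g. `"Chemicals & Drugs"`.
#' @return Logical flag.
#' @export
in_semantic_group <- function(map, concept_id, group) {
  group %in% semantic_groups(map, concept_id)
}

compose_row <- function(rec, dialect) {
  d <- .dialects[[dialect]]
  fields <- rep("", d$n_fields)
  put <- function(name, value) {
    if (!is.null(d[[name]]) && !is.na(value)) fields[d[[name]]] <<- value
  }
  put("concept_id", rec$concept_id)
  put("language", rec$language)
  put("string_id", rec$string_id)
  put("source_vocab", rec$source_vocab)
  put("term_type", rec$term_type)
  put("text", rec$text)
  put("suppress", "N")
  paste0(paste(fields, collapse = "|"), "|")
}

record_lines <- function(records, dialect) {
  vapply(seq_len(nrow(records)), function(i) {
    if (!is.na(records$raw[i])) records$raw[i]
    else compose_row(records[i, ], dialect)
  }, character(1L))
}

#' Write a concept-term table
#'
#' Original rows are written back byte-identically from their preserved raw
#' form; generated rows are composed in the requested dialect with their
#' synthetic string id (`R<rule>-<counter>`). If `sidecar_path` is given and
#' the lexicon carries suppressed records (as produced by [apply_rules()]),
#' those rows are written there in the same dialect with the suppressing rule
#' id appended as an extra field.
#'
#' @param lexicon A `lexicon`.
#' @param path Output path.
#' @param dialect `"mrconso"` or `"reduced"`.
#' @param sidecar_path Optional path for suppressed rows.
#' @return `path`, invisibly.
#' @export
write_concept_table <- function(lexicon, path, dialect = c("mrconso", "reduced"),
                                sidecar_path = NULL) {
  dialect <- match.arg(dialect)
  records <- lexicon_records(lexicon)
  write_utf8 <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  write_utf8(record_lines(records, dialect), path)
  if (!is.null(sidecar_path)) {
    supp <- attr(lexicon, "suppressed")
    lines <- if (is.null(supp) || nrow(supp) == 0L) character() else
      paste0(record_lines(supp, dialect), supp$suppressed_by, "|")
    write_utf8(lines, sidecar_path)
  }
  invisible(path)
}

#' Read a plain-text corpus
#'
#' One document (e.g. one title+abstract record) per line, UTF-8.
#'
#' @param path Corpus file path.
#' @return Character vector of documents; document ids are 1-based positions.
#' @export
read_corpus <- function(path) {
  readLines(path, encoding = "UTF-8", warn = FALSE)
}
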