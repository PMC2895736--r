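# Deterministic synthetic fixtures: small lexicon/semantic-type/corpus files
# with ground truth, so the whole pipeline is testable without a licensed
# terminology download. Lexicon words are drawn from a consonant-vowel
# syllable alphabet; corpus filler words carry a "zq" prefix that no lexicon
# word uses, so planted match counts are exact by construction.

#' Describe a synthetic fixture
#'
#' @param seed Integer seed; identical seed and counts give byte-identical
#'   fixture files.
#' @param rule_counts Named integer vector: how many terms to emit per
#'   rule-trigger category (`"1"`-`"9"`, `"S1"`-`"S8"`). Default one each.
#' @param distractors Number of terms that trigger no rule.
#' @param homonym_collisions Number of engineered cross-concept collisions
#'   (an invertible term whose inversion already names another concept).
#' @param duplicate_collisions Number of engineered same-concept collisions
#'   (an invertible term whose inversion is already a synonym of its own
#'   concept).
#' @param chem_decoys How many Chemicals & Drugs-typed copies of the
#'   boundary-parenthetical and long-term templates to emit (the rules with a
#'   chemical exclusion must fire on none of them).
#' @param corpus_docs Number of corpus documents emitted by
#'   [generate_corpus()].
#' @param plant_times Default number of planted occurrences per corpus term.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, rule_counts = NULL, distractors = 5L,
                         homonym_collisions = 1L, duplicate_collisions = 1L,
                         chem_decoys = 1L, corpus_docs = 5L, plant_times = 3L) {
  all_ids <- c(as.character(1:9), paste0("S", 1:8))
  counts <- stats::setNames(rep(1L, length(all_ids)), all_ids)
  if (!is.null(rule_counts)) {
    unknown <- setdiff(names(rule_counts), all_ids)
    if (length(unknown) > 0L) {
      stop("unknown rule id(s) in rule_counts: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    counts[names(rule_counts)] <- as.integer(rule_counts)
  }
  stopifnot(all(counts >= 0L), distractors >= 0L, homonym_collisions >= 0L,
            duplicate_collisions >= 0L, chem_decoys >= 0L, corpus_docs >= 1L,
            plant_times >= 0L)
  structure(list(
    seed = as.integer(seed), rule_counts = counts,
    distractors = as.integer(distractors),
    homonym_collisions = as.integer(homonym_collisions),
    duplicate_collisions = as.integer(duplicate_collisions),
    chem_decoys = as.integer(chem_decoys),
    corpus_docs = as.integer(corpus_docs),
    plant_times = as.integer(plant_times)
  ), class = "fixture_spec")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

.fix_consonants <- c("b", "d", "f", "g", "l", "m", "n", "p", "r", "t", "v")
.fix_vowels <- c("a", "e", "i", "o", "u")

# nonsense words guaranteed unique, not stop words, not inversion blockers,
# not suppression keywords, never "zq"-prefixed
make_words <- function(n, reserved = character()) {
  banned <- c(pubmed_stopwords(), rule_prepositions(),
              "other", "deprecated", "unknown", "obsolete", "miscellaneous",
              reserved)
  out <- character(0L)
  while (length(out) < n) {
    k <- sample(2:3, 1L)
    w <- paste0(sample(.fix_consonants, k, replace = TRUE),
                sample(.fix_vowels, k, replace = TRUE), collapse = "")
    if (w %in% banned || w %in% out) next
    out <- c(out, w)
  }
  out
}

cap <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

# term templates per rule category: list(text, expected candidate or NA)
fixture_template <- function(rule_id, w) {
  switch(rule_id,
    "1" = list(paste0(cap(w[1]), ", ", cap(w[2])),
               paste(cap(w[2]), cap(w[1]))),
    "2" = list(paste0(cap(w[1]), "'s ", w[2]), paste(cap(w[1]), w[2])),
    "3" = {
      lf <- paste(cap(w[1]), cap(w[2]), cap(w[3]))
      sf <- toupper(paste0(substr(w[1], 1, 1), substr(w[2], 1, 1),
                           substr(w[3], 1, 1)))
      list(paste0(lf, " (", sf, ")"), c(lf, sf))
    },
    "4" = list(paste0(cap(w[1]), " <", w[2], "> ", w[3]),
               paste(cap(w[1]), w[3])),
    "5" = {
      # choose a type name whose initial differs from the term's, so the
      # parenthetical can never pass the abbreviation pairing of rule 3
      tname <- if (substr(w[1], 1, 1) == "f") "Tissue" else "Finding"
      list(paste0(cap(w[1]), " (", tname, ")"), cap(w[1]))
    },
    "6" = list(paste0("(", w[1], ") ", cap(w[2]), " ", w[3]),
               paste(cap(w[2]), w[3])),
    "7" = list(paste0("[", w[1], "]", cap(w[2])), cap(w[2])),
    # three words inside the parentheses: a three-word parenthetical can never
    # qualify as a short form for rule 3, so only rule 8 fires
    "8" = list(paste0(cap(w[1]), " ", w[2], " (", w[3], " ", w[4], " ",
                      w[5], ")"),
               paste(cap(w[1]), w[2])),
    "9" = list(paste0(cap(w[1]), " ", w[2], " [", w[3], "]"),
               paste(cap(w[1]), w[2])),
    "S1" = list(paste0(sample(10:99, 1L), "*", sample(1:9, 1L), "/",
                       toupper(substr(w[1], 1, 1))), NA_character_),
    "S2" = list(paste0(cap(w[1]), " ", sample(1:9, 1L), "%"), NA_character_),
    "S3" = list(paste0(toupper(w[1]), " @@ ", toupper(w[2])), NA_character_),
    "S4" = list(paste0(cap(w[1]), " EC ", sample(1:6, 1L), ".",
                       sample(1:9, 1L), ".", sample(1:9, 1L), ".",
                       sample(1:99, 1L)), NA_character_),
    "S5" = list(paste(cap(w[1]), "unclassified", w[2]), NA_character_),
    "S6" = list(paste(cap(w[1]), "unspecified", w[2]), NA_character_),
    "S7" = list(paste("Other", w[1], w[2]), NA_character_),
    "S8" = list(paste(cap(w[1]), w[2], w[3], w[4], w[5], w[6]), NA_character_),
    stop("no template for rule ", rule_id)
  )
}

.template_words <- c("1" = 2L, "2" = 2L, "3" = 3L, "4" = 3L, "5" = 1L,
                     "6" = 3L, "7" = 2L, "8" = 5L, "9" = 3L,
                     "S1" = 1L, "S2" = 1L, "S3" = 2L, "S4" = 1L, "S5" = 2L,
                     "S6" = 2L, "S7" = 2L, "S8" = 6L)

# categories whose concepts are typed Chemicals & Drugs so that the
# rules they would otherwise also trigger are held off by the exclusion
.chem_typed_categories <- c("3", "5")
# rules with a Chemicals & Drugs exclusion, exercised by the decoys
.chem_excluded_rules <- c("6", "7", "8", "9", "S8")

#' Generate a synthetic lexicon fixture
#'
#' Emits a reduced-dialect concept-term table, an MRSTY-dialect semantic-type
#' table and a semantic-group mapping, containing per enabled category terms
#' built from templates that trigger exactly that rule, plus distractors that
#' trigger none, engineered duplicate/homonym collisions for guard testing,
#' and Chemicals & Drugs-typed decoys exercising the exclusions. A ground
#' truth table records the expected rule firing and guard outcome for every
#' term.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with file paths (`concept_table`, `semantic_types`,
#'   `semantic_groups`, `ground_truth_file`), the `ground_truth` tibble and
#'   the `spec`.
#' @export
generate_lexicon <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    cui_n <- 0L
    sui_n <- 0L
    next_cui <- function() {
      cui_n <<- cui_n + 1L
      sprintf("C%07d", cui_n)
    }
    next_sui <- function() {
      sui_n <<- sui_n + 1L
      sprintf("S%07d", sui_n)
    }
    chem_concepts <- character(0L)
    used_words <- character(0L)
    fresh_words <- function(n) {
      w <- make_words(n, reserved = used_words)
      used_words <<- c(used_words, w)
      w
    }
    add_term <- function(cui, text, category, rule_id, expected_action,
                         expected_text) {
      sid <- next_sui()
      rows[[length(rows) + 1L]] <<- sprintf("%s|ENG|%s|N|%s|", cui, sid, text)
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        concept_id = cui, string_id = sid, text = text, category = category,
        rule_id = rule_id, expected_action = expected_action,
        expected_text = expected_text
      )
      sid
    }

    for (rid in names(spec$rule_counts)) {
      k <- spec$rule_counts[[rid]]
      for (i in seq_len(k)) {
        w <- fresh_words(.template_words[[rid]])
        tpl <- fixture_template(rid, w)
        cui <- next_cui()
        if (rid %in% .chem_typed_categories) {
          chem_concepts <- c(chem_concepts, cui)
        }
        action <- if (startsWith(rid, "S")) "suppressed" else "added"
        add_term(cui, tpl[[1L]], rid, rid, action,
                 paste(tpl[[2L]], collapse = ";"))
      }
    }

    for (i in seq_len(spec$chem_decoys)) {
      for (rid in .chem_excluded_rules) {
        w <- fresh_words(.template_words[[rid]])
        tpl <- fixture_template(rid, w)
        cui <- next_cui()
        chem_concepts <- c(chem_concepts, cui)
        add_term(cui, tpl[[1L]], paste0("chem_decoy_", rid), rid, "none",
                 NA_character_)
      }
    }

    for (i in seq_len(spec$homonym_collisions)) {
      w <- fresh_words(2L)
      inverted <- paste(cap(w[2]), cap(w[1]))
      other <- next_cui()
      add_term(other, inverted, "homonym_holder", NA_character_, "none",
               NA_character_)
      cui <- next_cui()
      add_term(cui, paste0(cap(w[1]), ", ", cap(w[2])), "homonym_source",
               "1", "skipped_homonym", inverted)
    }

    for (i in seq_len(spec$duplicate_collisions)) {
      w <- fresh_words(2L)
      inverted <- paste(cap(w[2]), cap(w[1]))
      cui <- next_cui()
      add_term(cui, inverted, "duplicate_holder", NA_character_, "none",
               NA_character_)
      add_term(cui, paste0(cap(w[1]), ", ", cap(w[2])), "duplicate_source",
               "1", "skipped_duplicate", inverted)
    }

    for (i in seq_len(spec$distractors)) {
      w <- fresh_words(sample(2:4, 1L))
      cui <- next_cui()
      add_term(cui, paste(cap(w[1]), paste(w[-1], collapse = " ")),
               "distractor", NA_character_, "none", NA_character_)
    }

    truth <- do.call(rbind, truth)
    concept_table <- file.path(dir, "concepts.psv")
    writeLines(unlist(rows), concept_table, useBytes = TRUE)

    all_cuis <- unique(truth$concept_id)
    sty_rows <- vapply(all_cuis, function(cui) {
      if (cui %in% chem_concepts) {
        sprintf("%s|T121||Pharmacologic Substance||", cui)
      } else {
        sprintf("%s|T033||Finding||", cui)
      }
    }, character(1L))
    semantic_types <- file.path(dir, "mrsty.psv")
    writeLines(sty_rows, semantic_types, useBytes = TRUE)

    semantic_groups <- file.path(dir, "semgroups.psv")
    file.copy(pkg_extdata("semgroups.txt"), semantic_groups, overwrite = TRUE)

    ground_truth_file <- file.path(dir, "ground_truth.tsv")
    utils::write.table(truth, ground_truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")

    list(concept_table = concept_table, semantic_types = semantic_types,
         semantic_groups = semantic_groups,
         ground_truth_file = ground_truth_file, ground_truth = truth,
         spec = spec)
  })
}

# is `inner` a contiguous subsequence of `outer`? (token vectors)
is_token_subseq <- function(inner, outer) {
  ni <- length(inner)
  no <- length(outer)
  if (ni > no) return(FALSE)
  for (s in seq_len(no - ni + 1L)) {
    if (all(outer[s:(s + ni - 1L)] == inner)) return(TRUE)
  }
  FALSE
}

# surface variant within normalization equivalence: case changes and a
# hyphen for one internal space
surface_variant <- function(text) {
  style <- sample(c("asis", "upper", "lower"), 1L, prob = c(0.5, 0.25, 0.25))
  out <- switch(style, asis = text, upper = toupper(text), lower = tolower(text))
  if (grepl(" ", out, fixed = TRUE) && stats::runif(1L) < 0.3) {
    sp <- gregexpr(" ", out, fixed = TRUE)[[1L]]
    pos <- sp[sample(length(sp), 1L)]
    substr(out, pos, pos) <- "-"
  }
  out
}

#' Generate a synthetic corpus with planted term occurrences
#'
#' Documents consist of filler words drawn from a closed `zq`-prefixed
#' alphabet, disjoint by construction from every lexicon key, with the
#' requested terms planted at recorded token positions with recorded
#' multiplicities. Planted surfaces vary in case and punctuation within
#' normalization equivalence. Generation fails if any lexicon key is nested
#' inside a planted key (which would make planted counts inexact) or if the
#' filler alphabet is not disjoint from the lexicon.
#'
#' @param lexicon A `lexicon` (used for the disjointness and nesting checks).
#' @param terms Character vector of term texts to plant.
#' @param times Integer vector of occurrence counts, recycled over `terms`.
#' @param spec A [fixture_spec()]; supplies the seed and document count.
#' @param dir Optional output directory for `corpus.txt` and
#'   `corpus_ground_truth.tsv`.
#' @return List with `documents` (character vector), the `ground_truth`
#'   tibble (`doc_id`, `token_start`, `token_end` half-open, `key`,
#'   `surface`), and file paths when `dir` is given.
#' @export
generate_corpus <- function(lexicon, terms, times = NULL,
                            spec = fixture_spec(), dir = NULL) {
  lexicon <- as_lexicon(lexicon)
  stopifnot(length(terms) > 0L)
  times <- rep_len(if (is.null(times)) spec$plant_times else times,
                   length(terms))
  keys <- normalize_key(terms)
  stopifnot(all(nzchar(keys)))
  key_tokens <- strsplit(keys, " ", fixed = TRUE)
  lex_keys <- unique(lexicon$records$norm_key)
  lex_keys <- lex_keys[nzchar(lex_keys)]
  lex_tokens <- strsplit(lex_keys, " ", fixed = TRUE)
  if (any(startsWith(unlist(lex_tokens), "zq"))) {
    stop("lexicon keys collide with the 'zq' filler alphabet", call. = FALSE)
  }
  for (i in seq_along(keys)) {
    nested <- vapply(seq_along(lex_keys), function(j) {
      lex_keys[j] != keys[i] && is_token_subseq(lex_tokens[[j]], key_tokens[[i]])
    }, logical(1L))
    if (any(nested)) {
      stop(sprintf(
        "lexicon key '%s' is nested inside planted key '%s'; planted counts would be inexact",
        lex_keys[which(nested)[1L]], keys[i]
      ), call. = FALSE)
    }
  }

  with_seed(spec$seed + 1L, {
    filler <- function(n) {
      paste0("zq", vapply(seq_len(n), function(i) {
        paste0(sample(.fix_consonants, 2L, replace = TRUE),
               sample(.fix_vowels, 2L, replace = TRUE), collapse = "")
      }, character(1L)))
    }
    plant_idx <- rep(seq_along(terms), times)
    if (length(plant_idx) > 1L) plant_idx <- sample(plant_idx)
    doc_of <- if (length(plant_idx) > 0L) {
      rep_len(seq_len(spec$corpus_docs), length(plant_idx))
    } else {
      integer(0L)
    }
    docs <- character(spec$corpus_docs)
    gt <- list()
    for (d in seq_len(spec$corpus_docs)) {
      idx <- plant_idx[doc_of == d]
      pieces <- character(0L)
      cursor <- 0L
      pad <- filler(sample(1:3, 1L))
      pieces <- c(pieces, pad)
      cursor <- cursor + length(pad)
      for (ti in idx) {
        surf <- surface_variant(terms[ti])
        n_tok <- length(key_tokens[[ti]])
        gt[[length(gt) + 1L]] <- tibble::tibble(
          doc_id = d, token_start = cursor + 1L,
          token_end = cursor + 1L + n_tok, key = keys[ti], surface = surf
        )
        pieces <- c(pieces, surf)
        cursor <- cursor + n_tok
        pad <- filler(sample(1:3, 1L))
        pieces <- c(pieces, pad)
        cursor <- cursor + length(pad)
      }
      docs[d] <- paste(pieces, collapse = " ")
    }
    ground_truth <- if (length(gt)) do.call(rbind, gt) else tibble::tibble(
      doc_id = integer(), token_start = integer(), token_end = integer(),
      key = character(), surface = character()
    )
    out <- list(documents = docs, ground_truth = ground_truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$corpus_file <- file.path(dir, "corpus.txt")
      writeLines(docs, out$corpus_file, useBytes = TRUE)
      out$ground_truth_file <- file.path(dir, "corpus_ground_truth.tsv")
      utils::write.table(ground_truth, out$ground_truth_file, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
    out
  })
}

#' The frozen worked-example fixture
#'
#' A small, non-random concept table bundling the worked examples that the
#' rule set is specified by: one concept per example term, semantic typing for
#' the chemical-exclusion case, and an expectation table naming the rule and
#' output each term must produce.
#'
#' @return List with `concept_table`, `semantic_types`, `semantic_groups`
#'   paths and the `expected` tibble (`kind`, `rule_id`, `input`, `expected`,
#'   `in_chem_group`).
#' @export
golden_fixture <- function() {
  exp_path <- pkg_extdata("golden", "expected.tsv")
  expected <- tibble::as_tibble(utils::read.delim(
    exp_path, sep = "\t", quote = "", stringsAsFactors = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  ))
  expected$in_chem_group <- expected$in_chem_group == "TRUE"
  list(
    concept_table = pkg_extdata("golden", "concepts.psv"),
    semantic_types = pkg_extdata("golden", "mrsty.psv"),
    semantic_groups = pkg_extdata("semgroups.txt"),
    expected = expected
  )
}
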