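# Orchestration: filtering, deduplication, guarded rewriting, suppression,
# and the per-rule audit report.

rewrite_ids <- as.character(1:9)
suppression_ids <- paste0("S", 1:8)

rule_labels <- c(
  "1" = "syntactic_inversion", "2" = "possessives", "3" = "short_long_form",
  "4" = "angular_brackets", "5" = "semantic_type", "6" = "begin_parentheses",
  "7" = "begin_brackets", "8" = "end_parentheses", "9" = "end_brackets",
  "S1" = "short_token", "S2" = "dosages", "S3" = "at_sign", "S4" = "ec_numbers",
  "S5" = "any_classification", "S6" = "any_underspecification",
  "S7" = "miscellaneous", "S8" = "words_gt5"
)

#' Named rule profiles
#'
#' `"recommended"` enables the rules that survive manual evaluation of their
#' output (rewrite rules 1-5 and suppression rules S1-S7: the boundary
#' parenthetical rules generate too many over-general or wrong synonyms, and
#' the more-than-five-words rule removes mostly valuable terms).
#' `"full"` enables all seventeen rules.
#'
#' @return Named list of rule-id vectors.
#' @export
rule_profiles <- function() {
  list(
    recommended = c(as.character(1:5), paste0("S", 1:7)),
    full = c(rewrite_ids, suppression_ids)
  )
}

#' Build a rule configuration
#'
#' @param profile `"recommended"` or `"full"`; ignored when `rules` is given.
#' @param rules Optional explicit vector of rule ids (`"1"`-`"9"`,
#'   `"S1"`-`"S8"`); unknown ids are rejected.
#' @param stopwords,type_names,prepositions,units Resource overrides; defaults
#'   are the bundled lists.
#' @param keep_homonyms Keep homonym-colliding candidates in a sidecar table
#'   on the outcome (they are never written to the output lexicon).
#' @return A `rule_config` object.
#' @export
rule_config <- function(profile = c("recommended", "full"), rules = NULL,
                        stopwords = NULL, type_names = NULL,
                        prepositions = NULL, units = NULL,
                        keep_homonyms = FALSE) {
  if (is.null(rules)) {
    profile <- match.arg(profile)
    rules <- rule_profiles()[[profile]]
  } else {
    profile <- "custom"
    rules <- as.character(rules)
    unknown <- setdiff(rules, c(rewrite_ids, suppression_ids))
    if (length(unknown) > 0L) {
      stop("unknown rule id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    rules <- unique(rules)
  }
  structure(list(
    profile = profile,
    rules = rules,
    resources = list(
      stopwords = stopwords %||% pubmed_stopwords(),
      type_names = type_names %||% semantic_type_names(),
      prepositions = prepositions %||% rule_prepositions(),
      units = units %||% dosage_units()
    ),
    keep_homonyms = isTRUE(keep_homonyms)
  ), class = "rule_config")
}

#' Read a rule configuration from a YAML file
#'
#' Recognized keys: `profile`, `rules` (list of rule ids), `keep_homonyms`,
#' and under `resources:` the paths `stopwords`, `type_names`, `prepositions`
#' plus an inline token list `units`. Missing resource files raise an error
#' before any processing.
#'
#' @param path YAML file path.
#' @return A `rule_config` object.
#' @export
rule_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  res <- y$resources %||% list()
  load_res <- function(p, loader) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) {
      stop(sprintf("resource file '%s' not found", p), call. = FALSE)
    }
    loader(p)
  }
  rule_config(
    profile = y$profile %||% "recommended",
    rules = if (is.null(y$rules)) NULL else as.character(unlist(y$rules)),
    stopwords = load_res(res$stopwords, pubmed_stopwords),
    type_names = load_res(res$type_names, semantic_type_names),
    prepositions = load_res(res$prepositions, rule_prepositions),
    units = if (is.null(res$units)) NULL else as.character(unlist(res$units)),
    keep_homonyms = isTRUE(y$keep_homonyms)
  )
}

run_rewrite_rule <- function(rule_id, text, resources, in_chem_group) {
  switch(rule_id,
    "1" = rw_syntactic_inversion(text, resources$prepositions),
    "2" = rw_possessives(text),
    "3" = rw_short_long_form(text),
    "4" = rw_angular_brackets(text),
    "5" = rw_semantic_type(text, resources$type_names),
    "6" = rw_begin_parentheses(text, in_chem_group),
    "7" = rw_begin_brackets(text, in_chem_group),
    "8" = rw_end_parentheses(text, in_chem_group),
    "9" = rw_end_brackets(text, in_chem_group),
    stop("unknown rewrite rule id: ", rule_id, call. = FALSE)
  )
}

run_suppression_rule <- function(rule_id, text, resources, in_chem_group) {
  switch(rule_id,
    "S1" = sp_short_token(text, resources$stopwords),
    "S2" = sp_dosages(text, resources$units),
    "S3" = sp_at_sign(text),
    "S4" = sp_ec_number(text),
    "S5" = sp_any_classification(text),
    "S6" = sp_any_underspecification(text),
    "S7" = sp_miscellaneous(text),
    "S8" = sp_words_gt5(text, in_chem_group),
    stop("unknown suppression rule id: ", rule_id, call. = FALSE)
  )
}

#' Duplicate/homonym guard
#'
#' A candidate synonym is only added to a concept if its normalized key cannot
#' already be found among the strings of that concept or of any other concept
#' (case-insensitive comparison after punctuation removal). The guard returns
#' `"skipped_duplicate"` for a same-concept collision, `"skipped_homonym"`
#' when the key exists only under other concepts, `"skipped_empty"` when the
#' candidate normalizes to nothing, and `"added"` otherwise — in which case
#' the lexicon's key index is updated in place (the caller is responsible for
#' appending the record itself, as [apply_rules()] does).
#'
#' @param candidate Candidate term text.
#' @param concept_id Concept the candidate would be attached to.
#' @param lexicon A `lexicon`.
#' @return One of `"added"`, `"skipped_duplicate"`, `"skipped_homonym"`,
#'   `"skipped_empty"`.
#' @export
guard_candidate <- function(candidate, concept_id, lexicon) {
  key <- normalize_key(candidate)
  if (!nzchar(key)) return("skipped_empty")
  holders <- index_concepts(lexicon, key)
  if (concept_id %in% holders) return("skipped_duplicate")
  if (length(holders) > 0L) return("skipped_homonym")
  assign(key, c(holders, concept_id), envir = lexicon$index)
  "added"
}

empty_events <- function() {
  tibble::tibble(
    rule_id = character(), string_id = character(), concept_id = character(),
    action = character(), text = character(), via = character(),
    review = logical()
  )
}

#' Apply rewrite and suppression rules to a lexicon
#'
#' Pipeline: (1) default filtering and within-concept deduplication (skipped
#' when already done — both are idempotent); (2) the enabled rewrite rules, in
#' id order, over all original terms, every candidate passing through
#' [guard_candidate()]; (3) the enabled suppression rules, in id order, over
#' original and generated terms. A candidate that a currently enabled
#' suppression rule would remove is never added in the first place (logged as
#' `skipped_suppressed`), so re-running a profile on its own output neither
#' adds nor suppresses anything. Rewrite rules do not cascade: generated terms
#' are not fed back into the rewrite rules.
#'
#' @param x A `lexicon` or a term-record tibble.
#' @param semmap Optional `semtype_map` used for the Chemicals & Drugs
#'   exclusions; without it no concept is treated as a chemical.
#' @param config A `rule_config`.
#' @return A `rule_outcome`: list with `lexicon` (suppressed records excluded;
#'   carries the suppressed rows as an attribute for the sidecar), `report`
#'   (per-rule tallies), `events` (the full audit log) and `suppressed`.
#'   Homonym-colliding candidates are additionally collected under
#'   `homonyms` when `config$keep_homonyms` is set.
#' @export
apply_rules <- function(x, semmap = NULL, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  lex <- as_lexicon(if (inherits(x, "lexicon")) x$records else x)
  res <- config$resources
  rw_enabled <- intersect(rewrite_ids, config$rules)
  sp_enabled <- intersect(suppression_ids, config$rules)

  concepts <- unique(lex$records$concept_id)
  chem <- stats::setNames(rep(FALSE, length(concepts)), concepts)
  if (!is.null(semmap)) {
    chem[] <- vapply(concepts, in_semantic_group, logical(1L),
                     map = semmap, group = "Chemicals & Drugs")
  }

  ev <- list()
  log_event <- function(rule_id, string_id, concept_id, action, text,
                        via = NA_character_) {
    ev[[length(ev) + 1L]] <<- tibble::tibble(
      rule_id = rule_id, string_id = string_id, concept_id = concept_id,
      action = action, text = text, via = via,
      review = rule_id %in% c("3", "4")
    )
  }

  # candidate-level suppression: the id of the first enabled suppression rule
  # that would remove this text, or NA
  suppressing_rule <- function(text, in_chem) {
    for (sid in sp_enabled) {
      if (run_suppression_rule(sid, text, res, in_chem)$suppressed) return(sid)
    }
    NA_character_
  }

  originals <- lex$records
  generated <- list()
  homonyms <- list()
  counters <- stats::setNames(integer(length(rewrite_ids)), rewrite_ids)

  for (rid in rw_enabled) {
    for (j in seq_len(nrow(originals))) {
      cid <- originals$concept_id[j]
      cands <- run_rewrite_rule(rid, originals$text[j], res, chem[[cid]])
      for (cand in cands) {
        action <- guard_candidate(cand, cid, lex)
        if (action == "added") {
          sup_by <- suppressing_rule(cand, chem[[cid]])
          if (!is.na(sup_by)) {
            # roll the key back out of the index: the record is never created
            holders <- index_concepts(lex, normalize_key(cand))
            assign(normalize_key(cand), setdiff(holders, cid),
                   envir = lex$index)
            log_event(rid, originals$string_id[j], cid, "skipped_suppressed",
                      cand, via = sup_by)
            next
          }
          counters[rid] <- counters[rid] + 1L
          sid <- sprintf("R%s-%d", rid, counters[rid])
          generated[[length(generated) + 1L]] <- tibble::tibble(
            concept_id = cid, string_id = sid, text = cand,
            language = "ENG", source_vocab = originals$source_vocab[j],
            term_type = originals$term_type[j], suppressible = "N",
            provenance = "generated", rule_id = rid, raw = NA_character_,
            norm_key = normalize_key(cand)
          )
          log_event(rid, sid, cid, "added", cand)
        } else {
          log_event(rid, originals$string_id[j], cid, action, cand)
          if (action == "skipped_homonym" && config$keep_homonyms) {
            homonyms[[length(homonyms) + 1L]] <- tibble::tibble(
              rule_id = rid, source_string_id = originals$string_id[j],
              concept_id = cid, text = cand
            )
          }
        }
      }
    }
  }

  all_records <- rbind(originals, do.call(rbind, generated))
  suppressed_by <- rep(NA_character_, nrow(all_records))
  for (i in seq_len(nrow(all_records))) {
    cid <- all_records$concept_id[i]
    for (sid in sp_enabled) {
      v <- run_suppression_rule(sid, all_records$text[i], res, chem[[cid]])
      if (v$suppressed) {
        suppressed_by[i] <- sid
        log_event(sid, all_records$string_id[i], cid, "suppressed", v$trigger)
        break
      }
    }
  }

  out_records <- all_records[is.na(suppressed_by), , drop = FALSE]
  suppressed <- all_records[!is.na(suppressed_by), , drop = FALSE]
  if (nrow(suppressed) > 0L) {
    suppressed$suppressed_by <- suppressed_by[!is.na(suppressed_by)]
  } else {
    suppressed$suppressed_by <- character()
  }

  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  out_lex <- new_lexicon(out_records)
  attr(out_lex, "suppressed") <- suppressed

  outcome <- list(
    lexicon = out_lex,
    report = build_report(config$rules, events),
    events = events,
    suppressed = suppressed
  )
  if (config$keep_homonyms) {
    outcome$homonyms <- if (length(homonyms)) do.call(rbind, homonyms) else NULL
  }
  structure(outcome, class = "rule_outcome")
}

build_report <- function(rules, events) {
  count <- function(rid, action) sum(events$rule_id == rid & events$action == action)
  rows <- lapply(rules, function(rid) {
    added <- count(rid, "added")
    hom <- count(rid, "skipped_homonym")
    tibble::tibble(
      rule_id = rid,
      rule = unname(rule_labels[rid]),
      added = added,
      suppressed = count(rid, "suppressed"),
      skipped_duplicate = count(rid, "skipped_duplicate"),
      skipped_homonym = hom,
      skipped_empty = count(rid, "skipped_empty"),
      skipped_suppressed = count(rid, "skipped_suppressed"),
      homonyms = hom,
      homonym_pct = if (added + hom > 0L) 100 * hom / (added + hom) else 0
    )
  })
  do.call(rbind, rows)
}

#' @export
print.rule_outcome <- function(x, ...) {
  r <- x$report
  cat(sprintf("<rule_outcome> %d terms out (%d added, %d suppressed, %d homonym collisions)\n",
              nrow(x$lexicon$records), sum(r$added), sum(r$suppressed),
              sum(r$skipped_homonym)))
  print(r[r$added + r$suppressed + r$skipped_homonym + r$skipped_duplicate > 0, ])
  invisible(x)
}

#' Evaluate one rule in isolation
#'
#' Runs [apply_rules()] with only `rule_id` enabled and returns that rule's
#' report row (added / suppressed / homonym tallies); the full outcome is
#' attached as the `"outcome"` attribute.
#'
#' @inheritParams apply_rules
#' @param rule_id A single rule id.
#' @param config Optional `rule_config` supplying resources; its rule list is
#'   ignored.
#' @return One-row report tibble.
#' @export
single_rule_delta <- function(x, semmap = NULL, rule_id,
                              config = rule_config("full")) {
  cfg <- config
  cfg$rules <- as.character(rule_id)
  unknown <- setdiff(cfg$rules, c(rewrite_ids, suppression_ids))
  if (length(unknown) > 0L) {
    stop("unknown rule id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  outcome <- apply_rules(x, semmap, cfg)
  structure(outcome$report, outcome = outcome)
}
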